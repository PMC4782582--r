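#' Partition an image into K intensity clusters
#'
#' Runs Lloyd's K-means on the 1-D pixel intensity values and returns the
#' clusters as binary masks over the image grid.  The masks are pairwise
#' disjoint and their union is the full pixel domain; they are relabeled by
#' ascending cluster mean intensity so that cluster index `j` is
#' reproducible across runs (ties broken by the smaller original label).
#'
#' Initialization is deterministic by default: centers are placed at the
#' (k - 0.5)/K quantiles of the intensity distribution, so identical
#' `(image, K)` always give identical masks.  `init = "kmeans++"` draws
#' seeded random initial centers instead, for images whose intensity
#' distribution defeats quantile seeding.
#'
#' @param img a [gray_image()].
#' @param K number of clusters, >= 2 (K = 1 returns the identity partition
#'   unless `strict`).
#' @param seed integer seed (used by `init = "kmeans++"` only).
#' @param init `"quantile"` (default, deterministic) or `"kmeans++"`.
#' @param strict if `TRUE`, an image with fewer distinct intensities than K
#'   is an error; otherwise K is reduced with a warning.
#' @return An object of class `pixel_cluster_set`: list with `masks` (list
#'   of K logical matrices), `means` (ascending cluster mean intensities),
#'   `sizes`, `K`, `tot_withinss`.
#' @export
kmeans_segment <- function(img, K, seed = 0L, init = c("quantile", "kmeans++"),
                           strict = FALSE) {
  stopifnot(inherits(img, "gray_image"))
  init <- match.arg(init)
  if (!is_count(K, 1L))
    stop_spinocurve("K must be a positive integer", "validation_error")
  K <- as.integer(K)
  x <- as.vector(img$pixels)
  ux <- unique(x)
  if (length(ux) < K) {
    if (strict)
      stop_spinocurve(sprintf(
        "image has %d distinct intensities, fewer than K = %d",
        length(ux), K), "validation_error")
    warn_spinocurve(sprintf(
      "image has %d distinct intensities; reducing K from %d", length(ux), K),
      "reduced_K_warning")
    K <- length(ux)
  }

  if (K == 1L) {
    assign_k <- rep(1L, length(x))
    means <- mean(x)
    wss <- sum((x - means)^2)
  } else {
    centers <- if (init == "quantile") {
      ctr <- as.numeric(quantile(x, probs = (seq_len(K) - 0.5) / K,
                                 names = FALSE, type = 7))
      if (anyDuplicated(ctr)) {
        # mass quantiles collided (few distinct values): spread over uniques
        sux <- sort(ux)
        ctr <- sux[unique(pmax(1L, round(seq(1, length(sux), length.out = K))))]
        if (length(ctr) < K) ctr <- sux[seq_len(K)]
      }
      ctr
    } else {
      with_local_seed(seed, kmeanspp_centers(x, K))
    }
    km <- kmeans(x, centers = matrix(centers, ncol = 1), iter.max = 300L,
                 algorithm = "Lloyd")
    assign_k <- km$cluster
    means <- as.vector(km$centers)
    wss <- km$tot.withinss
  }

  # relabel by ascending mean; ties by smaller original label (order() is
  # stable for ties)
  ord <- order(means)
  relabel <- integer(length(ord)); relabel[ord] <- seq_along(ord)
  assign_k <- relabel[assign_k]
  means <- means[ord]

  masks <- lapply(seq_len(K), function(k) {
    m <- matrix(assign_k == k, nrow = img$height)
    m
  })
  structure(
    list(masks = masks, means = means,
         sizes = vapply(masks, sum, 0L), K = K, tot_withinss = wss),
    class = "pixel_cluster_set"
  )
}

# Seeded k-means++ initial centers on a numeric vector.
kmeanspp_centers <- function(x, K) {
  centers <- numeric(K)
  centers[1] <- x[sample.int(length(x), 1L)]
  d2 <- (x - centers[1])^2
  for (k in seq_len(K - 1L) + 1L) {
    if (all(d2 == 0)) { centers[k:K] <- centers[1]; break }
    centers[k] <- x[sample.int(length(x), 1L, prob = d2)]
    d2 <- pmin(d2, (x - centers[k])^2)
  }
  unique_jitter(centers, x)
}

unique_jitter <- function(ctr, x) {
  if (!anyDuplicated(ctr)) return(ctr)
  ux <- sort(unique(x))
  extra <- setdiff(ux, ctr)
  dup <- which(duplicated(ctr))
  ctr[dup] <- extra[seq_along(dup)]
  ctr
}

#' @export
print.pixel_cluster_set <- function(x, ...) {
  cat(sprintf("<pixel_cluster_set> K=%d clusters\n", x$K))
  for (k in seq_len(x$K))
    cat(sprintf("  S_%d: mean=%.4f, %d px\n", k, x$means[k], x$sizes[k]))
  invisible(x)
}

#' Select one cluster mask by intensity rank
#'
#' Cluster index `j` is 1-based by ascending mean intensity: `j = 1` is the
#' darkest cluster (always contains the global minimum-intensity pixel) and
#' `j = K` the brightest (contains the global maximum).
#'
#' @param clusters a `pixel_cluster_set` from [kmeans_segment()].
#' @param j cluster index, 1..K.
#' @return Logical matrix: the mask of cluster `S_j`.
#' @export
select_cluster <- function(clusters, j) {
  stopifnot(inherits(clusters, "pixel_cluster_set"))
  if (!is_count(j, 1L) || j > clusters$K)
    stop_spinocurve(sprintf("cluster index j = %s out of range 1..%d",
                            format(j), clusters$K), "index_error")
  clusters$masks[[j]]
}

#' Export cluster masks as 8-bit PNG files
#'
#' Writes one `S_<k>.png` per cluster (foreground 255, background 0).
#'
#' @param clusters a `pixel_cluster_set`.
#' @param dir output directory (created if needed).
#' @return Character vector of file paths, invisibly.
#' @export
export_cluster_masks <- function(clusters, dir) {
  stopifnot(inherits(clusters, "pixel_cluster_set"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(seq_len(clusters$K), function(k) {
    p <- file.path(dir, sprintf("S_%d.png", k))
    save_image_png(clusters$masks[[k]], p)
    p
  }, character(1))
  invisible(paths)
}
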