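#' Specification of a synthetic paired multi-omics benchmark
#'
#' The generator emulates paired multi-modal single-cell measurements with a
#' planted cluster structure: a shared low-dimensional latent state per cell
#' (cluster centroid plus unit within-cluster spread) is mapped through an
#' independent random linear map into each view's feature space, per-view
#' Gaussian measurement noise is added, negative values are clipped to zero
#' (zero is the data floor, as in sparse count-derived assays), entries are
#' zeroed independently with a per-view dropout probability, and each cell
#' profile is finally scaled to unit l2 norm — the O(1) inter-cell distance
#' scale that normalised expression workflows produce and that the model's
#' default Gaussian bandwidth and regularisation weights assume.
#' Defaults mirror a common simulated two-modality benchmark shape: 200 cells,
#' views of 1,000 and 5,000 features, 3 clusters.
#'
#' @param n_cells number of cells.
#' @param n_clusters number of planted clusters (sizes as equal as possible,
#'   all nonempty).
#' @param view_dims integer vector of per-view feature counts.
#' @param separation nonnegative scale of between-cluster centroid distances
#'   in latent space (centroid coordinates drawn N(0, separation^2); the
#'   within-cluster spread is fixed at 1 per latent dimension).
#' @param noise_sd per-view Gaussian noise standard deviation (recycled).
#' @param dropout per-view probability in [0, 1) of zeroing an entry (recycled).
#' @param mixing_rank dimension of the shared latent state.
#' @param seed integer seed; generation is fully deterministic given it.
#' @return a `synth_spec` list.
#' @export
synth_spec <- function(n_cells = 200L, n_clusters = 3L,
                       view_dims = c(1000L, 5000L), separation = 5,
                       noise_sd = 0.5, dropout = 0.3, mixing_rank = 10L,
                       seed = 0L) {
  V <- length(view_dims)
  noise_sd <- rep_len(noise_sd, V)
  dropout <- rep_len(dropout, V)
  stopifnot(n_cells >= n_clusters, n_clusters >= 1, all(view_dims >= 1),
            separation >= 0, all(noise_sd >= 0),
            all(dropout >= 0), all(dropout < 1), mixing_rank >= 1)
  structure(list(n_cells = as.integer(n_cells),
                 n_clusters = as.integer(n_clusters),
                 view_dims = as.integer(view_dims), separation = separation,
                 noise_sd = noise_sd, dropout = dropout,
                 mixing_rank = as.integer(mixing_rank),
                 seed = as.integer(seed)),
            class = "synth_spec")
}

#' Generate a synthetic paired multi-omics dataset
#'
#' @param spec a `synth_spec` (see [synth_spec()]).
#' @param latent_warp optional function applied to the n x r latent matrix
#'   before mixing (rows = cells); use it to plant nonlinear within-cluster
#'   structure such as curved manifolds.
#' @return a `multi_omics_dataset` whose `labels` field holds the planted
#'   cluster assignment.
#' @export
generate_multiomics <- function(spec = synth_spec(), latent_warp = NULL) {
  stopifnot(inherits(spec, "synth_spec"))
  with_seed(spec$seed, {
    n <- spec$n_cells; K <- spec$n_clusters; r <- spec$mixing_rank
    sizes <- diff(round(seq(0, n, length.out = K + 1)))
    labels <- rep.int(seq_len(K), sizes)
    centroids <- matrix(stats::rnorm(K * r, sd = spec$separation), K, r)
    H <- centroids[labels, , drop = FALSE] +
      matrix(stats::rnorm(n * r), n, r)            # n x r latent states
    if (!is.null(latent_warp)) H <- latent_warp(H)
    views <- vector("list", length(spec$view_dims))
    for (v in seq_along(spec$view_dims)) {
      m <- spec$view_dims[v]
      A <- matrix(stats::rnorm(m * r, sd = 1 / sqrt(r)), m, r)
      X <- A %*% t(H) + matrix(stats::rnorm(m * n, sd = spec$noise_sd[v]), m, n)
      X[X < 0] <- 0       # nonnegativity by clipping: zero is the data floor,
                          # so dropout zeros stay at the low end as in real data
      if (spec$dropout[v] > 0)
        X[matrix(stats::runif(m * n) < spec$dropout[v], m, n)] <- 0
      # emit unit-norm cell profiles: the model's default Gaussian bandwidth
      # and regularisation weights assume O(1) inter-cell distances, the scale
      # normalised expression workflows produce
      views[[v]] <- normalize_view(X, "l2")
    }
    names(views) <- paste0("view_", seq_along(views))
    assemble_dataset(views, labels = labels)
  })
}

#' Inject extra noise into one view
#'
#' Returns a copy of the dataset with additional Gaussian noise on a single
#' view, leaving the others untouched — useful for checking that the adaptive
#' per-view weight of a corrupted layer drops. With `feature_frac < 1` the
#' noise hits only a random subset of feature rows, emulating row-structured
#' technical artefacts (the corruption pattern the l2,1 noise term models).
#'
#' @param dataset a `multi_omics_dataset`.
#' @param view index of the view to corrupt.
#' @param noise_sd standard deviation of the added noise; 0 is a no-op.
#' @param feature_frac fraction of feature rows receiving noise, in (0, 1].
#' @param seed integer seed.
#' @return a `multi_omics_dataset`.
#' @export
corrupt_view <- function(dataset, view, noise_sd, feature_frac = 1, seed = 0L) {
  stopifnot(inherits(dataset, "multi_omics_dataset"),
            view >= 1, view <= dataset$n_views, noise_sd >= 0,
            feature_frac > 0, feature_frac <= 1)
  if (noise_sd == 0) return(dataset)
  X <- dataset$views[[view]]
  dataset$views[[view]] <- with_seed(seed, {
    rows <- if (feature_frac < 1)
      sample(nrow(X), max(1L, round(feature_frac * nrow(X))))
    else seq_len(nrow(X))
    X[rows, ] <- X[rows, ] +
      matrix(stats::rnorm(length(rows) * ncol(X), sd = noise_sd), length(rows))
    X
  })
  dataset
}
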