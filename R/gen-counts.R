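#' Simulate per-animal region cFos count tables with planted structure
#'
#' Emulates ClearMap-style region count exports for two treatment groups.
#' Counts are built from a latent Gaussian factor model: animals share a
#' per-module factor so that regions within a planted module have pairwise
#' correlation `within_module_rho` while between-module correlations are 0;
#' counts are `round(mean * (1 + cv * z))`, clamped at zero, so the latent
#' correlation carries through essentially unchanged. Group-2 region means
#' are multiplied by `group_mean_shift`.
#'
#' @param n_per_group Animals per group (>= 3).
#' @param regions Character vector of region names (non-empty).
#' @param planted_modules List of character vectors partitioning `regions`
#'   exactly once (no empty module).
#' @param within_module_rho Within-module correlation in \[0, 1).
#' @param group_mean_shift Multiplicative shift of group-2 means: scalar or
#'   named per-region vector (default 1).
#' @param seed RNG seed.
#' @param base_mean Baseline expected count per region (default 500).
#' @param cv Coefficient of variation of counts around the mean
#'   (default 0.25).
#' @param group_names Two group labels (default `c("SAC", "NIC")`).
#' @return A `region_counts` object: list with `counts` (animals x regions
#'   integer matrix), `group` (factor per animal), `regions`. Ground truth
#'   stores the planted module labels and parameters.
#' @export
gen_region_counts <- function(n_per_group, regions, planted_modules,
                              within_module_rho, group_mean_shift = 1,
                              seed = 1, base_mean = 500, cv = 0.25,
                              group_names = c("SAC", "NIC")) {
  if (length(regions) == 0) stop("regions must be non-empty", call. = FALSE)
  if (n_per_group < 3) stop("need >= 3 animals per group", call. = FALSE)
  stopifnot_scalar(within_module_rho, "within_module_rho",
                   lower = 0, upper = 1, strict_upper = TRUE)
  if (any(lengths(planted_modules) == 0)) {
    stop("empty module in partition", call. = FALSE)
  }
  flat <- unlist(planted_modules)
  if (length(flat) != length(regions) || !setequal(flat, regions) ||
      anyDuplicated(flat)) {
    stop("planted_modules must partition regions exactly once", call. = FALSE)
  }
  shift <- if (length(group_mean_shift) == 1) {
    stats::setNames(rep(group_mean_shift, length(regions)), regions)
  } else {
    if (!all(regions %in% names(group_mean_shift))) {
      stop("per-region group_mean_shift must name every region", call. = FALSE)
    }
    group_mean_shift[regions]
  }

  module_of <- stats::setNames(
    rep(seq_along(planted_modules), lengths(planted_modules)), flat
  )[regions]
  n_total <- 2L * n_per_group
  counts <- with_seed(seed, {
    z <- matrix(0, n_total, length(regions))
    fac <- matrix(stats::rnorm(n_total * length(planted_modules)),
                  n_total, length(planted_modules))
    eps <- matrix(stats::rnorm(n_total * length(regions)),
                  n_total, length(regions))
    for (j in seq_along(regions)) {
      z[, j] <- sqrt(within_module_rho) * fac[, module_of[j]] +
        sqrt(1 - within_module_rho) * eps[, j]
    }
    mu <- matrix(base_mean, n_total, length(regions), byrow = TRUE)
    mu[(n_per_group + 1):n_total, ] <-
      sweep(mu[(n_per_group + 1):n_total, , drop = FALSE], 2, shift, `*`)
    pmax(round(mu * (1 + cv * z)), 0)
  })
  mode(counts) <- "integer"
  colnames(counts) <- regions
  rownames(counts) <- c(paste0(group_names[1], "_", seq_len(n_per_group)),
                        paste0(group_names[2], "_", seq_len(n_per_group)))

  rc <- structure(
    list(
      counts = counts,
      group = factor(rep(group_names, each = n_per_group),
                     levels = group_names),
      regions = regions
    ),
    class = "region_counts"
  )
  attr(rc, "ground_truth") <- new_ground_truth(
    "region_counts",
    list(n_per_group = n_per_group, module_labels = as.integer(module_of),
         within_module_rho = within_module_rho, group_mean_shift = shift,
         base_mean = base_mean, cv = cv),
    seed
  )
  rc
}
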