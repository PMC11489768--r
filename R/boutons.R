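#' Background intensity as the histogram mode
#'
#' Estimates the image background as the mode of the intensity histogram
#' (256 bins), which is robust when objects occupy a small volume fraction.
#'
#' @param stack A `voxel_stack`.
#' @param bins Number of histogram bins (default 256).
#' @return Numeric scalar (bin midpoint of the modal bin).
#' @export
background_mode <- function(stack, bins = 256) {
  v <- as.vector(stack$data)
  h <- graphics::hist(v, breaks = bins, plot = FALSE)
  h$mids[which.max(h$counts)]
}

#' Detect bouton seeds as thresholded 3D local maxima
#'
#' A voxel is a seed if it is at least as intense as all of its 26
#' neighbors, its intensity reaches `threshold`, and (for plateaus of equal
#' intensity) it has the lowest linear index among its equal-valued
#' neighbors, so each plateau yields a single seed.
#'
#' @param stack A `voxel_stack`.
#' @param threshold Minimum seed intensity. `NULL` (default) uses
#'   background mode + `k_mad` robust standard deviations (MAD) of the
#'   intensities.
#' @param k_mad Multiplier for the automatic threshold (default 6, chosen so
#'   that the expected number of noise-only maxima above threshold stays near
#'   zero even in megavoxel stacks under Gaussian noise).
#' @param min_separation_um Minimum distance between retained seeds: when
#'   noise splits the flat top of one object into several nearby maxima,
#'   only the brightest within this radius is kept (default 0.4 um, below
#'   the size of a typical bouton).
#' @return Data frame `y`, `x`, `z` (voxel indices), `index` (linear),
#'   `intensity`, sorted by decreasing intensity; attribute `threshold`.
#'   Empty (with a warning) when the threshold exceeds the global maximum.
#' @export
detect_seeds <- function(stack, threshold = NULL, k_mad = 6,
                         min_separation_um = 0.4) {
  a <- stack$data
  d <- dim(a)
  if (is.null(threshold)) {
    bg <- background_mode(stack)
    threshold <- bg + k_mad * stats::mad(as.vector(a))
  }
  if (threshold > max(a)) {
    warning("seed threshold above the global maximum: no seeds")
  }
  pad <- array(-Inf, d + 2L)
  pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- a
  idx <- array(seq_along(a), d)
  idx_pad <- array(Inf, d + 2L)
  idx_pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- idx

  ge_all <- array(TRUE, d)
  eq_lower <- array(FALSE, d)
  for (dy in -1:1) for (dx in -1:1) for (dz in -1:1) {
    if (dy == 0 && dx == 0 && dz == 0) next
    nb <- pad[(2:(d[1] + 1)) + dy, (2:(d[2] + 1)) + dx, (2:(d[3] + 1)) + dz]
    nb_idx <- idx_pad[(2:(d[1] + 1)) + dy, (2:(d[2] + 1)) + dx,
                      (2:(d[3] + 1)) + dz]
    ge_all <- ge_all & (a >= nb)
    eq_lower <- eq_lower | (nb == a & nb_idx < idx)
  }
  sel <- which(ge_all & !eq_lower & a >= threshold)
  co <- arrayInd(sel, d)
  out <- data.frame(y = co[, 1], x = co[, 2], z = co[, 3],
                    index = sel, intensity = a[sel])
  out <- out[order(-out$intensity), , drop = FALSE]
  if (min_separation_um > 0 && nrow(out) > 1) {
    um <- sweep(sweep(as.matrix(out[, c("y", "x", "z")]), 2, 0.5), 2,
                stack$voxel_size_um, `*`)
    keep <- logical(nrow(out))
    for (i in seq_len(nrow(out))) {
      if (!any(keep)) {
        keep[i] <- TRUE
        next
      }
      dmin <- min(sqrt(rowSums(
        sweep(um[keep, , drop = FALSE], 2, um[i, ])^2
      )))
      keep[i] <- dmin >= min_separation_um
    }
    out <- out[keep, , drop = FALSE]
  }
  rownames(out) <- NULL
  attr(out, "threshold") <- threshold
  out
}

# Per-axis Gaussian sigma of the intensity profile through a voxel, by
# second moments of the background-subtracted positive part.
profile_sigmas <- function(a, seed_yxz, bg, voxel_size_um, half_width = 12L) {
  d <- dim(a)
  vapply(1:3, function(ax) {
    ctr <- seed_yxz[ax]
    rng <- max(1, ctr - half_width):min(d[ax], ctr + half_width)
    prof <- switch(ax,
      a[rng, seed_yxz[2], seed_yxz[3]],
      a[seed_yxz[1], rng, seed_yxz[3]],
      a[seed_yxz[1], seed_yxz[2], rng]
    )
    wgt <- pmax(prof - bg, 0)
    if (sum(wgt) <= 0) return(NA_real_)
    pos <- (rng - ctr) * voxel_size_um[ax]
    mu <- sum(wgt * pos) / sum(wgt)
    sqrt(sum(wgt * (pos - mu)^2) / sum(wgt))
  }, numeric(1))
}

#' Grow bouton objects around seeds
#'
#' Implements seeded block growing with an intensity-adaptive border. For
#' each seed, the local intensity distribution is treated as Gaussian and
#' the border threshold is set at the intensity enclosing the central
#' `area_fraction` of a Gaussian section: background + exp(-z^2/2) x
#' (peak - background) with z = qnorm((1 + area_fraction)/2) (z = 1.96 and
#' factor 0.146 at the default 0.95). Because the factor is relative to the
#' peak, boutons of similar size but different brightness are segmented at
#' similar sizes. Growth is breadth-first over 26-connectivity and a voxel
#' is included only if (1) its intensity reaches the border threshold,
#' (2) it is not brighter than the already-included voxel it extends
#' (monotone descent), and (3) it is validated by an already-included
#' neighbor closer to the seed (suppressing single-voxel noise tendrils).
#' Seeds are processed in decreasing peak order, so voxels contested
#' between objects go to the seed reached by the brighter descent path.
#'
#' @param stack A `voxel_stack`.
#' @param seeds Seed table from [detect_seeds()].
#' @param area_fraction Central Gaussian area fraction defining the border
#'   (default 0.95).
#' @param volume_bounds Length-2 numeric, retained object volume range in
#'   um^3 (default `c(0.01, 1.0)`).
#' @param background Background intensity; `NULL` (default) uses
#'   [background_mode()].
#' @return A `bouton_set`: list of objects, each with `seed` (y, x, z),
#'   `voxels` (matrix of voxel coordinates), `n_vox`, `volume_um3`,
#'   `centroid_um` (intensity-weighted), `peak`, `border_threshold`,
#'   `sigma_um`. Attributes: `n_dropped_degenerate`,
#'   `n_dropped_volume`, `background`.
#' @export
grow_boutons <- function(stack, seeds, area_fraction = 0.95,
                         volume_bounds = c(0.01, 1.0), background = NULL) {
  a <- stack$data
  d <- dim(a)
  vs <- stack$voxel_size_um
  if (is.null(background)) background <- background_mode(stack)
  z_cut <- stats::qnorm((1 + area_fraction) / 2)
  border_factor <- exp(-z_cut^2 / 2)

  offs <- as.matrix(expand.grid(dy = -1:1, dx = -1:1, dz = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]

  assigned <- integer(length(a))
  objects <- list()
  dropped_degenerate <- 0L
  dropped_volume <- 0L

  lin <- function(co) (co[, 3] - 1L) * d[1] * d[2] + (co[, 2] - 1L) * d[1] +
    co[, 1]

  for (si in seq_len(nrow(seeds))) {
    seed <- c(seeds$y[si], seeds$x[si], seeds$z[si])
    seed_lin <- seeds$index[si]
    if (assigned[seed_lin] != 0L) next  # swallowed by a brighter object
    peak <- a[seed_lin]
    thr <- background + border_factor * (peak - background)
    if (!is.finite(thr) || peak <= background) {
      dropped_degenerate <- dropped_degenerate + 1L
      next
    }
    sig <- profile_sigmas(a, seed, background, vs)
    if (any(!is.finite(sig)) || any(sig <= 0)) {
      dropped_degenerate <- dropped_degenerate + 1L
      next
    }
    id <- length(objects) + 1L
    seed_um <- (seed - 0.5) * vs

    assigned[seed_lin] <- id
    members <- matrix(seed, ncol = 3)
    queue <- matrix(seed, ncol = 3)
    dist2 <- function(co) {
      um <- sweep(sweep(co, 2, 0.5), 2, vs, `*`)
      rowSums(sweep(um, 2, seed_um)^2)
    }
    while (nrow(queue) > 0) {
      v <- queue[1, ]
      queue <- queue[-1, , drop = FALSE]
      v_lin <- (v[3] - 1L) * d[1] * d[2] + (v[2] - 1L) * d[1] + v[1]
      nb <- sweep(offs, 2, v, `+`)
      ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 & nb[, 2] <= d[2] &
        nb[, 3] >= 1 & nb[, 3] <= d[3]
      nb <- nb[ok, , drop = FALSE]
      if (nrow(nb) == 0) next
      nb_lin <- lin(nb)
      cand <- assigned[nb_lin] == 0L & a[nb_lin] >= thr & a[nb_lin] <= a[v_lin]
      if (!any(cand)) next
      nb <- nb[cand, , drop = FALSE]
      nb_lin <- nb_lin[cand]
      # criterion 3: validated by a member neighbor closer to the seed; the
      # voxel v we grow from qualifies when it is closer than the candidate
      dv <- sum(((v - 0.5) * vs - seed_um)^2)
      dn <- dist2(nb)
      val <- dv < dn
      if (!all(val)) {
        for (k in which(!val)) {
          nbk <- sweep(offs, 2, nb[k, ], `+`)
          okk <- nbk[, 1] >= 1 & nbk[, 1] <= d[1] & nbk[, 2] >= 1 &
            nbk[, 2] <= d[2] & nbk[, 3] >= 1 & nbk[, 3] <= d[3]
          nbk <- nbk[okk, , drop = FALSE]
          if (nrow(nbk) == 0) next
          mem <- assigned[lin(nbk)] == id
          if (any(mem) && any(dist2(nbk[mem, , drop = FALSE]) < dn[k])) {
            val[k] <- TRUE
          }
        }
      }
      if (!any(val)) next
      nb <- nb[val, , drop = FALSE]
      nb_lin <- nb_lin[val]
      assigned[nb_lin] <- id
      members <- rbind(members, nb)
      queue <- rbind(queue, nb)
    }

    vol <- nrow(members) * prod(vs)
    if (vol < volume_bounds[1] || vol > volume_bounds[2]) {
      assigned[lin(members)] <- -1L  # consumed, but filtered out
      dropped_volume <- dropped_volume + 1L
      next
    }
    w <- a[lin(members)] - background
    um <- sweep(sweep(members, 2, 0.5), 2, vs, `*`)
    centroid <- colSums(um * w) / sum(w)
    objects[[id]] <- list(
      seed = seed, voxels = members, n_vox = nrow(members),
      volume_um3 = vol, centroid_um = centroid, peak = peak,
      border_threshold = thr, sigma_um = sig
    )
  }

  objects <- Filter(Negate(is.null), objects)
  structure(objects, class = "bouton_set",
            n_dropped_degenerate = dropped_degenerate,
            n_dropped_volume = dropped_volume,
            background = background)
}

#' Bouton density per standard volume
#'
#' Normalizes the bouton count to a standard volume of 10 x 10 x 10 um
#' (1000 um^3) so stacks of different sizes are comparable.
#'
#' @param boutons A `bouton_set` (or plain count).
#' @param stack The `voxel_stack` the boutons came from.
#' @return List: `count`, `stack_volume_um3`, `density_per_1000um3`.
#' @export
bouton_density <- function(boutons, stack) {
  count <- if (is.numeric(boutons)) boutons else length(boutons)
  vol <- prod(dim(stack$data)) * prod(stack$voxel_size_um)
  if (vol <= 0) stop("stack volume must be positive", call. = FALSE)
  list(count = count, stack_volume_um3 = vol,
       density_per_1000um3 = count * 1000 / vol)
}

#' Match segmented boutons to planted ground-truth spots
#'
#' Greedy nearest-centroid matching within `tol_um`; each truth spot and
#' each segmented object is used at most once.
#'
#' @param truth_spots Data frame with `y_um`, `x_um`, `z_um`.
#' @param boutons A `bouton_set`.
#' @param tol_um Match tolerance in um (default 0.5).
#' @return List: `n_true`, `n_found`, `tp`, `precision`, `recall`.
#' @export
match_boutons <- function(truth_spots, boutons, tol_um = 0.5) {
  n_true <- nrow(truth_spots)
  n_found <- length(boutons)
  if (n_true == 0 || n_found == 0) {
    return(list(n_true = n_true, n_found = n_found, tp = 0L,
                precision = if (n_found == 0) NA_real_ else 0,
                recall = if (n_true == 0) NA_real_ else 0))
  }
  truth <- as.matrix(truth_spots[, c("y_um", "x_um", "z_um")])
  found <- t(vapply(boutons, function(b) b$centroid_um, numeric(3)))
  dd <- as.matrix(stats::dist(rbind(truth, found)))
  dd <- dd[seq_len(n_true), n_true + seq_len(n_found), drop = FALSE]
  tp <- 0L
  while (TRUE) {
    m <- which(dd == min(dd), arr.ind = TRUE)[1, , drop = TRUE]
    if (dd[m[1], m[2]] > tol_um) break
    tp <- tp + 1L
    dd[m[1], ] <- Inf
    dd[, m[2]] <- Inf
    if (all(!is.finite(dd))) break
  }
  list(n_true = n_true, n_found = n_found, tp = tp,
       precision = tp / n_found, recall = tp / n_true)
}
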