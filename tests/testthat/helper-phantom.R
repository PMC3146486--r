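# Shared fixture builders and independent oracles.  Everything is generated
# in code at test time; no binary fixtures.

full_mask <- function(grid) mask_volume(array(TRUE, dim = grid))

# stack with per-subject volumes produced by fun(i)
make_stack <- function(n, grid = c(4L, 4L, 4L),
                       fun = function(i) array(i, dim = grid), ...) {
  volume_stack(lapply(seq_len(n), fun), ...)
}

subset_stack <- function(stack, sel) {
  volume_stack(stack$data[, , , sel, drop = FALSE], affine = stack$affine,
               subject_ids = stack$subject_ids[sel])
}

# generate a phantom and age-correct it with a control-only fit
fit_and_correct <- function(spec) {
  ph <- generate_cohort(spec)
  mask <- full_mask(spec$grid)
  ctrl <- ph$cohort$group == "control"
  field <- fit_age_model(subset_stack(ph$stack, ctrl),
                         ph$cohort$age[ctrl], mask)
  corrected <- apply_correction(ph$stack, ph$cohort$age, field)
  list(ph = ph, mask = mask, field = field, corrected = corrected,
       ctrl = ctrl)
}

# Independent flood-fill (BFS) connected-component oracle.
flood_fill_labels <- function(flag, connectivity) {
  shape <- dim(flag)
  offs <- agedetrend:::connectivity_offsets(connectivity)
  labels <- array(0L, dim = shape)
  lab <- 0L
  for (start in which(flag)) {
    if (labels[start] != 0L) next
    lab <- lab + 1L
    queue <- start
    labels[start] <- lab
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      ijk <- arrayInd(v, shape)
      for (r in seq_len(nrow(offs))) {
        nb <- ijk + offs[r, ]
        if (any(nb < 1L) || any(nb > shape)) next
        li <- nb[1] + (nb[2] - 1L) * shape[1] + (nb[3] - 1L) * shape[1] * shape[2]
        if (flag[li] && labels[li] == 0L) {
          labels[li] <- lab
          queue <- c(queue, li)
        }
      }
    }
  }
  labels
}

# partitions agree up to label renaming
same_partition <- function(la, lb) {
  fa <- la[la > 0 | lb > 0]; fb <- lb[la > 0 | lb > 0]
  if (any((fa == 0) != (fb == 0))) return(FALSE)
  length(unique(paste(fa, fb))) == length(unique(fa)) &&
    length(unique(paste(fa, fb))) == length(unique(fb))
}

# Direct (brute-force) separable Gaussian convolution oracle, zero padding.
direct_gaussian_3d <- function(vol, fwhm, voxel = c(1, 1, 1)) {
  shape <- dim(vol)
  sigma <- fwhm / (voxel * 2 * sqrt(2 * log(2)))
  kern <- lapply(sigma, function(s) {
    r <- max(1L, ceiling(4 * s))
    k <- exp(-((-r):r)^2 / (2 * s^2))
    list(k = k / sum(k), r = r)
  })
  out <- array(0, dim = shape)
  for (x in 1:shape[1]) for (y in 1:shape[2]) for (z in 1:shape[3]) {
    acc <- 0
    for (dx in -kern[[1]]$r:kern[[1]]$r) {
      sx <- x - dx; if (sx < 1 || sx > shape[1]) next
      for (dy in -kern[[2]]$r:kern[[2]]$r) {
        sy <- y - dy; if (sy < 1 || sy > shape[2]) next
        for (dz in -kern[[3]]$r:kern[[3]]$r) {
          sz <- z - dz; if (sz < 1 || sz > shape[3]) next
          acc <- acc + vol[sx, sy, sz] *
            kern[[1]]$k[dx + kern[[1]]$r + 1] *
            kern[[2]]$k[dy + kern[[2]]$r + 1] *
            kern[[3]]$k[dz + kern[[3]]$r + 1]
        }
      }
    }
    out[x, y, z] <- acc
  }
  out
}
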