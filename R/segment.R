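#' Parameters for semi-supervised autofluorescence segmentation
#'
#' @param neighborhood Lattice connectivity for the voxel graph (6 or 26;
#'   only 6 is implemented, the 26 option falls back to 6 with a warning).
#' @param affinity_sigma_intensity Gaussian affinity bandwidth on intensity
#'   differences; `NULL` = set from the median absolute edge difference.
#' @param affinity_window Window (voxels) for the local-variance texture
#'   feature entering the affinity.
#' @param n_eigenvectors Spectral-embedding dimension used to label graph
#'   components that contain no seed.
#' @param label_prior_weight Ridge added to the graph Laplacian so the
#'   propagation stays well-posed on seedless components.
#' @param diffusion List `conductance`, `step`, `iterations` for the
#'   edge-preserving (Perona–Malik) smoothing of class-probability maps.
#' @param downsample Integer factors (x, y, z) for the coarse lattice the
#'   spectral/propagation step runs on; labels are upsampled by nearest
#'   neighbour and refined at full resolution.
#' @param fg_k Foreground threshold in robust sigmas above the slice
#'   background.
#' @param af_over_k,af_lat_max In-band fiber recovery: a voxel inside the
#'   autofluorescence region is reclassified as fiber when its local
#'   lateral high-pass contrast exceeds the slice's band level by
#'   `af_over_k` robust sigmas, the suprathreshold blob is laterally
#'   thinner than `af_lat_max` µm, and the blob connects to dermal fiber.
#' @param core_mad_margin Additional noise margin (robust sigmas) on the
#'   core threshold, suppressing borderline halo voxels in deep slices.
#' @param core_frac Fraction of the local structure peak (above
#'   background) a voxel must exceed to count as structure core; keeps the
#'   segmented tube width close to the physical fiber width despite the
#'   point-spread halo.
#' @return A `segmentation_params` list.
#' @export
segmentation_params <- function(neighborhood = 6L,
                                affinity_sigma_intensity = NULL,
                                affinity_window = c(5L, 5L, 3L),
                                n_eigenvectors = 8L,
                                label_prior_weight = 1e-6,
                                diffusion = list(conductance = 0.2,
                                                 step = 0.15,
                                                 iterations = 5L),
                                downsample = c(4L, 4L, 2L),
                                fg_k = 4, core_frac = 0.5,
                                core_mad_margin = 2,
                                af_over_k = 3, af_lat_max = 1.5) {
  if (!is.null(affinity_sigma_intensity) && affinity_sigma_intensity <= 0)
    stopf("affinity sigma must be positive")
  if (diffusion$iterations < 0) stopf("diffusion iterations must be >= 0")
  structure(list(neighborhood = neighborhood,
                 affinity_sigma_intensity = affinity_sigma_intensity,
                 affinity_window = as.integer(affinity_window),
                 n_eigenvectors = as.integer(n_eigenvectors),
                 label_prior_weight = label_prior_weight,
                 diffusion = diffusion,
                 downsample = as.integer(downsample), fg_k = fg_k,
                 core_frac = core_frac, core_mad_margin = core_mad_margin,
                 af_over_k = af_over_k, af_lat_max = af_lat_max),
            class = "segmentation_params")
}

otsu_threshold <- function(x, nbins = 256) {
  h <- hist(x, breaks = seq(min(x), max(x), length.out = nbins + 1),
            plot = FALSE)
  w <- h$counts / sum(h$counts)
  mids <- h$mids
  best <- c(-Inf, mids[1])
  for (k in 1:(nbins - 1)) {
    w0 <- sum(w[1:k]); w1 <- 1 - w0
    if (w0 < 1e-9 || w1 < 1e-9) next
    m0 <- sum(w[1:k] * mids[1:k]) / w0
    m1 <- sum(w[(k + 1):nbins] * mids[(k + 1):nbins]) / w1
    v <- w0 * w1 * (m0 - m1)^2
    if (v > best[1]) best <- c(v, (mids[k] + mids[k + 1]) / 2)
  }
  best[2]
}

# Per-slice robust background stats with band-dominated slices interpolated
# from fiber-only slices (the epidermal band floods its slices' medians).
slice_background <- function(vol, dims) {
  sn <- dims[1] * dims[2]
  med <- numeric(dims[3]); madv <- numeric(dims[3])
  for (z in seq_len(dims[3])) {
    sl <- vol[(z - 1) * sn + seq_len(sn)]
    med[z] <- median(sl)
    madv[z] <- stats::mad(sl)
  }
  band <- med > 2.5 * median(med)
  if (any(band) && any(!band)) {
    zz <- seq_len(dims[3])
    med[band] <- stats::approx(zz[!band], med[!band], zz[band],
                               rule = 2)$y
    madv[band] <- stats::approx(zz[!band], madv[!band], zz[band],
                                rule = 2)$y
  }
  list(median = med, mad = pmax(madv, 1e-6), band_slice = band)
}

# Shared foreground machinery: smoothed volume, per-slice noise floor,
# PSF-aware "core" mask (voxels above a fraction of the local structure
# peak, so the segmented width tracks the pre-blur tube) and its thickness.
foreground_features <- function(stack, params) {
  dims <- dim(stack$data)
  vox <- stack$voxel_size
  vol <- cpp_gauss_blur3d(as.numeric(stack$data), dims, c(0.25, 0.25, 0.15))
  bg <- slice_background(vol, dims)
  sn <- dims[1] * dims[2]
  floor_z <- rep(bg$median + params$fg_k * bg$mad, each = sn)
  localmax <- cpp_box_max(vol, dims, c(7L, 7L, 3L))
  medrep <- rep(bg$median, each = sn)
  core <- vol > pmax(floor_z, medrep + params$core_mad_margin *
                       rep(bg$mad, each = sn) +
                       params$core_frac * (localmax - medrep))
  bright <- vol > floor_z
  thick <- cpp_chamfer3d(as.integer(core), dims, vox)
  list(vol = vol, dims = dims, vox = vox, bg = bg, floor_z = floor_z,
       bright = bright, core = core, thickness = thick, slice_n = sn)
}

# Dermal structure analysis shared by seeding and refinement: connected
# components of the dermal core mask, plus the appendage mask = voxels of
# hair-bearing components (>= 20 laterally massive voxels) within 5 um of
# their massive core, so fiber branches merely touching a hair survive.
dermal_structure <- function(ff, zmask) {
  core_derm <- ff$core & !zmask
  ccd <- cpp_label_cc26(as.integer(core_derm), ff$dims)
  ncc <- max(ccd)
  out <- list(core_derm = core_derm, ccd = ccd, ncc = ncc,
              memb = integer(), app_mask = logical(length(core_derm)))
  if (ncc == 0) return(out)
  memb <- which(ccd > 0L)
  cc_m <- ccd[memb]
  th_m <- ff$thickness[memb]
  nthick <- tabulate(cc_m[th_m > 2.45], nbins = ncc)
  vetoed <- nthick >= 20L
  app_mask <- logical(length(core_derm))
  thick_vox <- memb[th_m > 2.45 & vetoed[cc_m]]
  if (length(thick_vox) > 0) {
    notthick <- rep(1L, length(core_derm))
    notthick[thick_vox] <- 0L
    dist_thick <- cpp_chamfer3d(notthick, ff$dims, ff$vox, FALSE)
    app_mask <- core_derm & dist_thick <= 5
  }
  out$memb <- memb
  out$cc_m <- cc_m
  out$th_m <- th_m
  out$app_mask <- app_mask
  out
}

#' Automatic weak-supervision seeding
#'
#' Heuristic seeds so the pipeline can run unattended: the laminar
#' high-intensity band near the surface is seeded as epidermal
#' autofluorescence, thick bright structures outside it as appendage, thin
#' bright structures as fiber, and sub-median voxels as background.
#'
#' @param stack An `image_stack` (16-bit, stitched).
#' @param params A [segmentation_params()].
#' @return Integer array of seed labels, `-1` = unseeded, else class
#'   0 (background), 1 (fiber), 2 (epidermal autofluorescence),
#'   3 (appendage).
#' @export
auto_seed_labels <- function(stack, params = segmentation_params()) {
  ff <- foreground_features(stack, params)
  wide_thick <- cpp_chamfer3d(as.integer(ff$bright), ff$dims, ff$vox)
  zmask <- rep(ff$bg$band_slice, each = ff$slice_n)
  seeds <- rep(-1L, prod(ff$dims))
  seeds[ff$bright & zmask & wide_thick > 2.6] <- 2L
  # classify whole dermal components, not voxels: a hair's tapering tip is
  # locally thin but belongs to a component that is thick somewhere
  dsx <- dermal_structure(ff, zmask)
  if (dsx$ncc > 0) {
    seeds[dsx$app_mask] <- 3L
    fib <- dsx$memb[!dsx$app_mask[dsx$memb] & dsx$th_m < 1.6]
    seeds[fib] <- 1L
  }
  seeds[ff$vol < rep(ff$bg$median, each = ff$slice_n)] <- 0L
  array(seeds, ff$dims)
}

coarse_pool_seeds <- function(seeds, dims, ds, cdims) {
  n_c <- prod(cdims)
  votes <- matrix(0, n_c, 4)
  for (cls in 0:3) {
    ind <- as.numeric(seeds == cls)
    votes[, cls + 1] <- cpp_downsample_mean(ind, dims, ds)
  }
  any_seed <- rowSums(votes) > 0
  lab <- rep(-1L, n_c)
  lab[any_seed] <- max.col(votes[any_seed, , drop = FALSE]) - 1L
  lab
}

lattice_edges <- function(cd) {
  n <- prod(cd)
  id <- seq_len(n) - 1L
  x <- id %% cd[1]; y <- (id %/% cd[1]) %% cd[2]; z <- id %/% (cd[1] * cd[2])
  e <- list()
  if (cd[1] > 1) {
    m <- x < cd[1] - 1
    e[[1]] <- cbind(id[m], id[m] + 1L)
  }
  if (cd[2] > 1) {
    m <- y < cd[2] - 1
    e[[2]] <- cbind(id[m], id[m] + cd[1])
  }
  if (cd[3] > 1) {
    m <- z < cd[3] - 1
    e[[3]] <- cbind(id[m], id[m] + cd[1] * cd[2])
  }
  do.call(rbind, e) + 1L
}

#' Semi-supervised spectral-graph segmentation of a stack
#'
#' Builds a lattice graph over a (optionally downsampled) intensity volume
#' with Gaussian affinities on intensity and local-window variance, and
#' propagates sparse seed labels by solving the harmonic (graph-Laplacian)
#' regularization problem per class. Components that contain no seed are
#' labelled via a spectral embedding of the graph (nearest seeded node in
#' embedding space). Class-probability maps are smoothed with an
#' edge-preserving nonlinear diffusion before the final per-voxel argmax,
#' which is refined at full resolution: bright voxels adopt the foreground
#' class of their region, dark voxels become background, and seeded voxels
#' always keep their seed label.
#'
#' @param stack An `image_stack`.
#' @param seeds Integer array (dims of the stack), `-1` unseeded, classes
#'   0–3; `NULL` = automatic seeding ([auto_seed_labels()]).
#' @param params A [segmentation_params()].
#' @return Integer label array (0 background, 1 fiber, 2 epidermal
#'   autofluorescence, 3 appendage).
#' @export
semi_supervised_segment <- function(stack, seeds = NULL,
                                    params = segmentation_params()) {
  dims <- dim(stack$data)
  vox <- stack$voxel_size
  if (is.null(seeds)) seeds <- auto_seed_labels(stack, params)
  if (!all(dim(seeds) == dims)) stopf("seed dims must match the stack")
  sv <- as.integer(seeds)
  if (!any(sv >= 0L)) stopf("seeding error: no seed voxels supplied")
  if (any(sv > 3L)) stopf("label error: seed class outside {0,1,2,3}")
  vol <- cpp_gauss_blur3d(as.numeric(stack$data), dims, c(0.7, 0.7, 0.4))
  ds <- pmin(params$downsample, dims)
  cdims <- as.integer(ceiling(dims / ds))
  cvol <- cpp_downsample_mean(vol, dims, ds)
  tex <- cpp_box_meanvar(vol, dims, params$affinity_window)$var
  ctex <- sqrt(pmax(cpp_downsample_mean(tex, dims, ds), 0))
  if (params$neighborhood != 6L)
    warning("only 6-connectivity is implemented; using 6")
  ed <- lattice_edges(cdims)
  dI <- abs(cvol[ed[, 1]] - cvol[ed[, 2]])
  dT <- abs(ctex[ed[, 1]] - ctex[ed[, 2]])
  sI <- params$affinity_sigma_intensity %||% max(median(dI), 1e-6)
  sT <- max(median(dT), 1e-6)
  w <- exp(-0.5 * (dI / sI)^2) * exp(-0.5 * (dT / sT)^2) + 1e-6
  n_c <- prod(cdims)
  W <- Matrix::sparseMatrix(i = c(ed[, 1], ed[, 2]),
                            j = c(ed[, 2], ed[, 1]),
                            x = c(w, w), dims = c(n_c, n_c))
  clab <- coarse_pool_seeds(sv, dims, ds, cdims)
  classes <- sort(unique(sv[sv >= 0L]))
  lab_idx <- which(clab >= 0L)
  unl_idx <- which(clab < 0L)
  P <- matrix(0, n_c, length(classes))
  colnames(P) <- as.character(classes)
  for (j in seq_along(classes))
    P[lab_idx, j] <- as.numeric(clab[lab_idx] == classes[j])
  if (length(unl_idx) > 0 && length(lab_idx) > 0) {
    Dg <- Matrix::Diagonal(x = Matrix::rowSums(W))
    L <- Dg - W
    Luu <- L[unl_idx, unl_idx] +
      Matrix::Diagonal(length(unl_idx), params$label_prior_weight)
    B <- W[unl_idx, lab_idx, drop = FALSE] %*%
      P[lab_idx, , drop = FALSE]
    Fu <- as.matrix(Matrix::solve(Luu, B))
    P[unl_idx, ] <- Fu
    P <- resolve_seedless_components(P, W, clab, classes, cvol, ctex,
                                     params)
  }
  # edge-preserving smoothing of the class-probability maps
  it <- params$diffusion$iterations
  if (it > 0) {
    for (j in seq_len(ncol(P)))
      P[, j] <- cpp_perona_malik3d(P[, j], cdims, it,
                                   params$diffusion$conductance,
                                   params$diffusion$step)
  }
  coarse_lab <- classes[max.col(P, ties.method = "first")]
  # nearest-neighbour upsample of the coarse region labels
  ix <- pmin(cdims[1], (seq_len(dims[1]) - 1) %/% ds[1] + 1)
  iy <- pmin(cdims[2], (seq_len(dims[2]) - 1) %/% ds[2] + 1)
  iz <- pmin(cdims[3], (seq_len(dims[3]) - 1) %/% ds[3] + 1)
  region <- as.integer(array(coarse_lab, cdims)[ix, iy, iz, drop = FALSE])
  # full-resolution refinement
  ff <- foreground_features(stack, params)
  out <- integer(prod(dims))
  zband <- rep(ff$bg$band_slice, each = ff$slice_n)
  out[ff$bright & region == 2L] <- 2L
  out[ff$bright & region == 3L] <- 3L
  # inside band-dominated slices everything bright defaults to the band
  out[ff$bright & zband & region != 3L] <- 2L
  # dermal structure: each connected core component takes the majority
  # propagated class of its non-appendage voxels (fallback: fiber); the
  # appendage mask from the thickness analysis overrides locally
  dsx <- dermal_structure(ff, zband)
  is_fiber_cc <- logical(prod(dims))
  if (dsx$ncc > 0) {
    memb <- dsx$memb
    cc_m <- dsx$cc_m
    keepv <- !dsx$app_mask[memb]
    reg_m <- region[memb]
    votes <- matrix(0L, dsx$ncc, 3)
    votes_all <- matrix(0L, dsx$ncc, 3)
    for (cl in 1:3) {
      votes[, cl] <- tabulate(cc_m[keepv & reg_m == cl], nbins = dsx$ncc)
      votes_all[, cl] <- tabulate(cc_m[reg_m == cl], nbins = dsx$ncc)
    }
    cls_cc <- rep(1L, dsx$ncc)
    has_vote <- rowSums(votes) > 0
    cls_cc[has_vote] <- max.col(votes[has_vote, , drop = FALSE],
                                ties.method = "first")
    # components entirely inside the appendage mask still follow their
    # propagated class when it is unambiguous
    only_app <- !has_vote & rowSums(votes_all) > 0
    cls_cc[only_app] <- max.col(votes_all[only_app, , drop = FALSE],
                                ties.method = "first")
    out[memb] <- cls_cc[cc_m]
    # the appendage mask overrides fiber/background calls, but a component
    # the propagation firmly labels autofluorescence keeps that class
    out[dsx$app_mask & out != 2L] <- 3L
    is_fiber_cc[memb] <- out[memb] == 1L
  }
  # fibers crossing the band: voxels well above the local band level whose
  # suprathreshold blob is laterally thin and 3D-connected to dermal fiber
  af_reg <- (region == 2L | zband) & ff$bright
  if (any(af_reg) && any(is_fiber_cc)) {
    sn <- ff$slice_n
    # local lateral high-pass: a crossing fiber is a narrow bright
    # addition on the smooth band texture, so it survives subtraction of
    # the local mean while the texture itself does not
    hp <- ff$vol - cpp_box_meanvar(ff$vol, dims, c(11L, 11L, 1L))$mean
    over_v <- logical(prod(dims))
    over_h <- logical(prod(dims))
    for (z in seq_len(dims[3])) {
      idx <- (z - 1) * sn + seq_len(sn)
      az <- af_reg[idx]
      if (!any(az)) next
      hz <- hp[idx][az]
      vz <- ff$vol[idx][az]
      if (isTRUE(params$af_use_hp %||% TRUE))
        over_h[idx][az] <- hz > median(hz) +
          params$af_over_k * stats::mad(hz)
      over_v[idx][az] <- vz > median(vz) + params$af_over_k * stats::mad(vz)
    }
    lat_um <- c(stack$voxel_size[1], stack$voxel_size[2], 1e6)
    keep_v <- over_v &
      cpp_chamfer3d(as.integer(over_v), dims, lat_um) <= params$af_lat_max
    keep_h <- over_h &
      cpp_chamfer3d(as.integer(over_h), dims, lat_um) <= params$af_lat_max
    over <- keep_v | keep_h
    # a fiber pierces a slice as a compact blob; the bright rims around
    # band gaps are extended arcs - drop large per-slice blobs
    sl_dims <- c(dims[1], dims[2], 1L)
    max_blob <- 25L
    for (z in seq_len(dims[3])) {
      idx <- (z - 1) * sn + seq_len(sn)
      oz <- over[idx]
      if (!any(oz)) next
      cs <- cpp_label_cc26(as.integer(oz), sl_dims)
      sizes <- tabulate(cs[cs > 0])
      big <- which(sizes > max_blob)
      if (length(big)) over[idx][cs %in% big] <- FALSE
    }
    # connectivity to dermal fiber; ascending fibers may break for a
    # slice or two, so bridge along z only before the component check
    un_dil <- cpp_box_max(as.numeric(over | is_fiber_cc), dims,
                          c(1L, 1L, 5L)) > 0.5
    cc2 <- cpp_label_cc26(as.integer(un_dil), dims)
    good <- unique(cc2[is_fiber_cc])
    out[over & (cc2 %in% good)] <- 1L
    # fill short vertical breaks between accepted in-band fiber voxels so
    # the traced ascent is continuous: a fiber is continuous, its detected
    # cross-sections may not be
    fib <- out == 1L & zband
    if (any(fib)) {
      fibarr <- array(fib, dims)
      brarr <- array(ff$bright, dims)
      outarr <- array(out, dims)
      zs <- which(ff$bg$band_slice)
      idxs <- which(apply(fibarr, c(1, 2), any), arr.ind = TRUE)
      for (r in seq_len(nrow(idxs))) {
        colz <- which(fibarr[idxs[r, 1], idxs[r, 2], ])
        if (length(colz) < 2) next
        for (j in seq_len(length(colz) - 1)) {
          gap <- (colz[j] + 1):(colz[j + 1] - 1)
          if (length(gap) == 0 || colz[j + 1] - colz[j] > 5) next
          if (all(brarr[idxs[r, 1], idxs[r, 2], gap]))
            outarr[idxs[r, 1], idxs[r, 2], gap] <- 1L
        }
      }
      out <- as.integer(outarr)
    }
    # structures that pierce the skin surface are appendages or gap rims,
    # never intra-epidermal free endings (which terminate inside the
    # epidermis): drop in-band fiber chains touching the top planes
    fib2 <- array(out == 1L & zband, dims)
    if (any(fib2)) {
      cc3 <- array(cpp_label_cc26(as.integer(fib2), dims), dims)
      top <- unique(as.integer(cc3[, , 1:min(3, dims[3])]))
      top <- top[top > 0]
      if (length(top)) {
        kill <- (cc3 %in% top) & fib2
        out[kill] <- 2L
      }
    }
  }
  out[sv >= 0L] <- sv[sv >= 0L]
  array(out, dims)
}

# Label seedless graph components through the spectral embedding: each gets
# the class of the nearest seeded node in embedding space.
resolve_seedless_components <- function(P, W, clab, classes, cvol, ctex,
                                        params) {
  g <- igraph::graph_from_adjacency_matrix(W, mode = "undirected",
                                           weighted = TRUE)
  comp <- igraph::components(g)$membership
  seeded_comp <- unique(comp[clab >= 0L])
  lost <- which(!(comp %in% seeded_comp))
  if (length(lost) == 0) return(P)
  k <- min(params$n_eigenvectors, max(2L, length(classes)))
  emb <- tryCatch(
    with_seed(1L, igraph::embed_laplacian_matrix(g, no = k, type = "DAD")$X),
    error = function(e) cbind(cvol, ctex))
  seeded <- which(clab >= 0L)
  nn <- cpp_grid_nn(cbind(emb[seeded, 1], emb[seeded, min(2, ncol(emb))],
                          0)[, 1:3, drop = FALSE] * 1.0,
                    cbind(emb[lost, 1], emb[lost, min(2, ncol(emb))],
                          0)[, 1:3, drop = FALSE] * 1.0,
                    cell = 0.1)
  for (i in seq_along(lost)) {
    cls <- clab[seeded[nn$idx[i]]]
    P[lost[i], ] <- as.numeric(classes == cls)
  }
  P
}

#' Edge-preserving diffusion smoothing of a volume
#'
#' Perona–Malik-type nonlinear diffusion with conductance
#' `g(du) = 1 / (1 + (du/K)^2)`; used to smooth class-probability maps
#' before the final labelling. `iterations = 0` returns the input unchanged.
#'
#' @param volume 3D numeric array (or vector with `dims`).
#' @param params List with `conductance` (K), `step` (dt) and `iterations`.
#' @param dims Dims when `volume` is a plain vector.
#' @return Smoothed array of the same shape.
#' @export
diffusion_smooth <- function(volume,
                             params = list(conductance = 0.2, step = 0.15,
                                           iterations = 5L),
                             dims = dim(volume)) {
  if (params$iterations < 0) stopf("iterations must be >= 0")
  if (params$iterations == 0) return(volume)
  out <- cpp_perona_malik3d(as.numeric(volume), as.integer(dims),
                            params$iterations, params$conductance,
                            params$step)
  if (!is.null(dim(volume))) array(out, dim(volume)) else out
}

#' Remove autofluorescence and appendage voxels from a stack
#'
#' Voxels labelled epidermal autofluorescence (2) or appendage (3) — and
#' their one-voxel halo, which the point spread leaves bright — are
#' replaced by the median of background-labelled voxels in the same z slice
#' (global background median when a slice has none); fiber-labelled voxels
#' are never touched.
#'
#' @param stack An `image_stack`.
#' @param labels Label array of matching dims.
#' @return A cleaned `image_stack`.
#' @export
remove_autofluorescence <- function(stack, labels) {
  dims <- dim(stack$data)
  if (!all(dim(labels) == dims)) stopf("label dims must match the stack")
  v <- stack$data
  lb <- as.integer(labels)
  glob <- if (any(lb == 0L)) median(v[lb == 0L]) else 0
  # grow the removal mask by one voxel to suppress the bright rim the
  # point-spread halo leaves around removed structures; fiber-labelled
  # voxels are protected
  rem <- cpp_box_max(as.numeric(lb == 2L | lb == 3L), dims,
                     c(3L, 3L, 3L)) > 0
  rem <- rem & lb != 1L
  sn <- dims[1] * dims[2]
  for (z in seq_len(dims[3])) {
    idx <- (z - 1) * sn + seq_len(sn)
    lz <- lb[idx]
    rep_mask <- rem[idx]
    if (!any(rep_mask)) next
    bgm <- if (any(lz == 0L)) median(v[idx][lz == 0L]) else glob
    v[idx][rep_mask] <- bgm
  }
  image_stack(v, voxel_size = stack$voxel_size, bit_depth = stack$bit_depth,
              session = stack$session)
}
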