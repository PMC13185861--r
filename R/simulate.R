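#' Specify a synthetic trajectory
#'
#' Builds the specification consumed by [simulate_trajectory()]. Motifs
#' mirror the repertoire seen in freely moving ciliated organoids: constant-
#' radius circling, radius-modulated circling, spirograph-like superpositions
#' of several harmonics, wall following, and immobility. All motifs except
#' `boundary_follow` are sums of sinusoids per axis; `x(t)` and `y(t)` are
#' `center + sum_i A_i cos(2 pi f_i t + phi_i)` plus i.i.d. Gaussian jitter.
#'
#' @param motif One of `"stationary"`, `"circle"`, `"modulated_circle"`,
#'   `"multi_harmonic"`, `"boundary_follow"`.
#' @param components For `multi_harmonic` (and optionally to override other
#'   motifs): a list with elements `x` and `y`, each a data.frame with
#'   columns `amplitude` (mm), `frequency` (Hz), `phase` (rad).
#' @param center Trajectory centre `c(x, y)` in mm.
#' @param duration Recording length in s (> 0). Default 1800, a 30-min trial.
#' @param sampling_rate Sampling rate in Hz (> 0). Default 1.
#' @param noise_sd Coordinate jitter SD in mm (>= 0). Default 0.
#' @param seed Integer RNG seed; the same seed reproduces the output bit for
#'   bit.
#' @param radius,frequency Convenience parameters for the circle motifs:
#'   orbit radius (mm) and revolution frequency (Hz). Defaults 0.5 mm and
#'   1/120 Hz (a 2-min revolution).
#' @param arena For `boundary_follow`: `c(width, height)` of the rectangular
#'   well in mm (perimeter is centred on `center`). Default `c(4, 4)`.
#' @param speed For `boundary_follow`: travel speed along the wall in mm/s.
#'   Default 0.05.
#' @return A `trajectory_sim_spec` object.
#' @export
trajectory_sim_spec <- function(motif = c("circle", "stationary", "modulated_circle",
                                          "multi_harmonic", "boundary_follow"),
                                components = NULL, center = c(0, 0),
                                duration = 1800, sampling_rate = 1,
                                noise_sd = 0, seed = 1L,
                                radius = 0.5, frequency = 1 / 120,
                                arena = c(4, 4), speed = 0.05) {
  motif <- match.arg(motif)
  stop_if_not_scalar_number(duration, "duration", positive = TRUE)
  stop_if_not_scalar_number(sampling_rate, "sampling_rate", positive = TRUE)
  stop_if_not_scalar_number(noise_sd, "noise_sd")
  if (noise_sd < 0) stop("noise_sd must be >= 0")

  if (is.null(components)) {
    components <- switch(
      motif,
      stationary = list(x = empty_components(), y = empty_components()),
      circle = list(
        x = data.frame(amplitude = radius, frequency = frequency, phase = 0),
        y = data.frame(amplitude = radius, frequency = frequency, phase = -pi / 2)),
      modulated_circle = list(
        x = data.frame(amplitude = c(radius, 0.3 * radius),
                       frequency = c(frequency, frequency / 4),
                       phase = c(0, 0)),
        y = data.frame(amplitude = c(radius, 0.3 * radius),
                       frequency = c(frequency, frequency / 4),
                       phase = c(-pi / 2, -pi / 2))),
      multi_harmonic = stop("multi_harmonic requires an explicit 'components' list"),
      boundary_follow = list(x = empty_components(), y = empty_components()))
  }
  if (motif != "boundary_follow") {
    for (ax in c("x", "y")) {
      comp <- components[[ax]]
      if (!is.data.frame(comp) ||
          !all(c("amplitude", "frequency", "phase") %in% names(comp)))
        stop("components$", ax,
             " must be a data.frame with amplitude, frequency, phase")
      if (nrow(comp) && any(comp$frequency >= sampling_rate / 2))
        stop(sprintf(
          "component frequency %.4g Hz is at or above the Nyquist frequency %.4g Hz",
          max(comp$frequency), sampling_rate / 2))
    }
  }
  structure(list(motif = motif, components = components, center = as.numeric(center),
                 duration = duration, sampling_rate = sampling_rate,
                 noise_sd = noise_sd, seed = as.integer(seed),
                 arena = as.numeric(arena), speed = speed),
            class = "trajectory_sim_spec")
}

empty_components <- function()
  data.frame(amplitude = numeric(), frequency = numeric(), phase = numeric())

#' Simulate a trajectory with known spectral ground truth
#'
#' @param spec A [trajectory_sim_spec()].
#' @return A [trajectory()] whose noiseless coordinates equal the specified
#'   sums of sinusoids exactly (or the perimeter walk for `boundary_follow`).
#' @examples
#' tr <- simulate_trajectory(trajectory_sim_spec("circle", seed = 7))
#' range(sqrt(tr$x^2 + tr$y^2))  # constant radius 0.5 mm
#' @export
simulate_trajectory <- function(spec) {
  stopifnot(inherits(spec, "trajectory_sim_spec"))
  n <- round(spec$duration * spec$sampling_rate)
  t <- (seq_len(n) - 1) / spec$sampling_rate
  if (spec$motif == "boundary_follow") {
    w <- spec$arena[1L]; h <- spec$arena[2L]
    p <- 2 * (w + h)
    s <- (spec$speed * t) %% p
    x <- numeric(n); y <- numeric(n)
    seg1 <- s < w
    seg2 <- !seg1 & s < w + h
    seg3 <- !seg1 & !seg2 & s < 2 * w + h
    seg4 <- !(seg1 | seg2 | seg3)
    x[seg1] <- s[seg1];            y[seg1] <- 0
    x[seg2] <- w;                  y[seg2] <- s[seg2] - w
    x[seg3] <- w - (s[seg3] - w - h); y[seg3] <- h
    x[seg4] <- 0;                  y[seg4] <- h - (s[seg4] - 2 * w - h)
    x <- x - w / 2 + spec$center[1L]
    y <- y - h / 2 + spec$center[2L]
  } else {
    x <- rep(spec$center[1L], n)
    y <- rep(spec$center[2L], n)
    cx <- spec$components$x; cy <- spec$components$y
    for (i in seq_len(nrow(cx)))
      x <- x + cx$amplitude[i] * cos(2 * pi * cx$frequency[i] * t + cx$phase[i])
    for (i in seq_len(nrow(cy)))
      y <- y + cy$amplitude[i] * cos(2 * pi * cy$frequency[i] * t + cy$phase[i])
  }
  if (spec$noise_sd > 0) {
    local_seed(spec$seed, {
      x <- x + stats::rnorm(n, 0, spec$noise_sd)
      y <- y + stats::rnorm(n, 0, spec$noise_sd)
    })
  }
  trajectory(x, y, spec$sampling_rate, pixel_scale = 1,
             source = paste0("sim_", spec$motif, "_seed", spec$seed))
}

#' Specify a synthetic pooled expression experiment
#'
#' The generative model mirrors pooled bulk RNA-seq of whole organoids: each
#' gene has a baseline abundance drawn once from a log-normal distribution,
#' each *individual* organoid draws its expression from a log-normal with
#' that gene's mean and a group-specific individual-level coefficient of
#' variation, and each sequenced pool reports the arithmetic mean of its
#' individuals. The spread across a group's pools therefore estimates the
#' standard error of the mean, which is what the pooled-CV analysis inverts.
#'
#' @param n_genes Number of genes.
#' @param groups Named list; each element is a list with `n_pools` (>= 2 for
#'   downstream CV), `pool_size` (individuals per pool; scalar or vector of
#'   length `n_pools`) and `individual_cv` (unitless; scalar or vector of
#'   length `n_genes` for abundance-stratified CV).
#' @param gene_mean_meanlog,gene_mean_sdlog Log-mean and log-SD of the
#'   baseline abundance distribution. Defaults `log(50)` and 1.5, giving an
#'   FPKM-like right-skewed abundance range.
#' @param seed Integer RNG seed.
#' @return A `pooled_sim_spec` object.
#' @export
pooled_sim_spec <- function(n_genes, groups,
                            gene_mean_meanlog = log(50), gene_mean_sdlog = 1.5,
                            seed = 1L) {
  if (n_genes < 1L) stop("n_genes must be >= 1")
  if (is.null(names(groups)) || any(names(groups) == ""))
    stop("groups must be a named list")
  for (g in groups) {
    if (any(g$pool_size < 1)) stop("pool_size must be >= 1")
    if (any(g$individual_cv < 0)) stop("individual_cv must be >= 0")
    if (!(length(g$individual_cv) %in% c(1L, n_genes)))
      stop("individual_cv must be a scalar or length n_genes")
  }
  structure(list(n_genes = as.integer(n_genes), groups = groups,
                 gene_mean_meanlog = gene_mean_meanlog,
                 gene_mean_sdlog = gene_mean_sdlog, seed = as.integer(seed)),
            class = "pooled_sim_spec")
}

#' Simulate a pooled count matrix with known ground truth
#'
#' @param spec A [pooled_sim_spec()].
#' @return A [pooled_counts()] object (genes x pools) with group labels and
#'   per-pool individual counts. With `individual_cv = 0` every pool value
#'   equals the gene's baseline mean exactly.
#' @export
simulate_pooled_expression <- function(spec) {
  stopifnot(inherits(spec, "pooled_sim_spec"))
  local_seed(spec$seed, {
    ng <- spec$n_genes
    m <- stats::rlnorm(ng, spec$gene_mean_meanlog, spec$gene_mean_sdlog)
    cols <- list(); group <- character(); pool_n <- integer()
    for (gname in names(spec$groups)) {
      g <- spec$groups[[gname]]
      sizes <- rep_len(g$pool_size, g$n_pools)
      cv <- rep_len(g$individual_cv, ng)
      sdlog <- sqrt(log(1 + cv^2))
      meanlog <- log(m) - sdlog^2 / 2  # arithmetic mean of individuals = m
      for (j in seq_len(g$n_pools)) {
        draws <- matrix(stats::rlnorm(ng * sizes[j], meanlog, sdlog),
                        nrow = ng, ncol = sizes[j])
        cols[[paste0(gname, j)]] <- rowMeans(draws)
        group <- c(group, gname)
        pool_n <- c(pool_n, sizes[j])
      }
    }
    values <- do.call(cbind, cols)
    rownames(values) <- sprintf("gene%05d", seq_len(ng))
    pc <- pooled_counts(values, group = group, pool_n = pool_n)
    attr(pc, "true_gene_mean") <- m
    pc
  })
}

#' Specify a synthetic elliptical body mask
#'
#' @param major_axis,minor_axis Full axis lengths in mm
#'   (`0 < minor_axis <= major_axis`).
#' @param orientation Major-axis angle in rad, counter-clockwise from the
#'   grid x (column) direction.
#' @param pixel_scale Pixel scale in mm/px.
#' @param dim Grid size `c(rows, cols)` in px; the ellipse, centred on the
#'   grid, must fit inside it.
#' @return A `mask_sim_spec` object.
#' @export
mask_sim_spec <- function(major_axis, minor_axis, orientation = 0,
                          pixel_scale = 0.01, dim = c(256, 256)) {
  if (minor_axis <= 0 || minor_axis > major_axis)
    stop("need 0 < minor_axis <= major_axis")
  stop_if_not_scalar_number(pixel_scale, "pixel_scale", positive = TRUE)
  dim <- as.integer(dim)
  half_extent <- major_axis / 2 / pixel_scale
  if (2 * half_extent > min(dim))
    stop("ellipse does not fit inside the grid")
  structure(list(major_axis = major_axis, minor_axis = minor_axis,
                 orientation = orientation, pixel_scale = pixel_scale,
                 dim = dim),
            class = "mask_sim_spec")
}

#' Rasterise the specified ellipse into a binary mask
#'
#' A pixel is foreground when its centre falls inside the ellipse.
#'
#' @param spec A [mask_sim_spec()].
#' @return A [shape_mask()] object.
#' @export
simulate_mask <- function(spec) {
  stopifnot(inherits(spec, "mask_sim_spec"))
  nr <- spec$dim[1L]; nc <- spec$dim[2L]
  # pixel centres in mm, origin at grid centre; columns = x, rows = y
  xs <- ((seq_len(nc) - 0.5) - nc / 2) * spec$pixel_scale
  ys <- ((seq_len(nr) - 0.5) - nr / 2) * spec$pixel_scale
  a <- spec$major_axis / 2; b <- spec$minor_axis / 2
  co <- cos(spec$orientation); si <- sin(spec$orientation)
  X <- matrix(xs, nr, nc, byrow = TRUE)
  Y <- matrix(ys, nr, nc)
  u <- (X * co + Y * si) / a
  v <- (-X * si + Y * co) / b
  shape_mask(u^2 + v^2 <= 1, pixel_scale = spec$pixel_scale)
}

#' Write a pooled count matrix as TSV plus YAML metadata
#'
#' @param pc A [pooled_counts()] object.
#' @param path Output TSV path (gene id column + one column per pool).
#' @param meta_path Optional YAML path for group labels and pool sizes
#'   (default: `path` with `.yaml`).
#' @return `path`, invisibly.
#' @export
write_pooled_counts <- function(pc, path, meta_path = NULL) {
  stopifnot(inherits(pc, "pooled_counts"))
  d <- data.frame(gene_id = rownames(pc$values), pc$values,
                  check.names = FALSE)
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  meta_path <- meta_path %||% sub("\\.tsv$", ".yaml", path)
  yaml::write_yaml(list(group = as.list(stats::setNames(pc$group, colnames(pc$values))),
                        pool_n = as.list(stats::setNames(pc$pool_n, colnames(pc$values)))),
                   meta_path)
  invisible(path)
}

#' Read a pooled count matrix written by [write_pooled_counts()]
#'
#' @param path TSV path (first column gene ids).
#' @param meta_path YAML path with `group` and `pool_n` maps keyed by pool
#'   name.
#' @return A [pooled_counts()] object.
#' @export
read_pooled_counts <- function(path, meta_path = NULL) {
  meta_path <- meta_path %||% sub("\\.tsv$", ".yaml", path)
  d <- utils::read.delim(path, check.names = FALSE)
  values <- as.matrix(d[, -1L, drop = FALSE])
  rownames(values) <- d[[1L]]
  meta <- yaml::read_yaml(meta_path)
  pooled_counts(values,
                group = unlist(meta$group)[colnames(values)],
                pool_n = unlist(meta$pool_n)[colnames(values)])
}
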