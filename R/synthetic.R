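#' Specification for a synthetic observation dataset
#'
#' States the world the generator emulates.  In \code{"sfx"} mode every
#' non-absent reflection's observations are drawn from
#' ExGauss(\code{mu_b}, \code{sigma_b}, tau(hkl)): a shared diffuse/background
#' Gaussian response plus an exponential Bragg tail whose mean follows a
#' Wilson-like falloff \eqn{\tau(hkl) = S\,e^{-B/(2d^2)}\,F_{hkl}} with a
#' log-normal per-reflection structure-factor modulation.  Systematic
#' absences (generated on the P2(1)2(1)2(1) screw-axis rule) carry no
#' exponential component.  In \code{"synchrotron"} mode each reflection is
#' near-symmetric Gaussian with a Wilson-decaying mean.
#'
#' Defaults: the published orthorhombic cell (57.9, 84.8, 384.3 A) to a
#' 3.5 A limit; multiplicities uniform on 5..160 (the observed M range);
#' background (0, 600) counts and S = 6000 so fitted parameter magnitudes
#' land in the observed ranges (sigma_exg ~ 500-1200, tau_exg ~ 700-9000).
#'
#' @param n_reflections number of unique reflections (absences included).
#' @param cell a \code{\link{unit_cell}}.
#' @param d_min resolution limit (Angstrom).
#' @param multiplicity_range integer range for per-reflection multiplicity.
#' @param mu_b,sigma_b background Gaussian location/scale (counts).
#' @param scale_s overall Bragg tail scale S (counts).
#' @param b_true Wilson-like B for the tail falloff (Angstrom^2).
#' @param lognorm_sdlog sdlog of the structure-factor modulation.
#' @param absent_fraction fraction of reflections generated as absences.
#' @param n_frames number of simulated frames observations scatter over.
#' @param mode \code{"sfx"} or \code{"synchrotron"}.
#' @param seed RNG seed.
#' @return list of class \code{exg_sim_spec}.
#' @export
simulation_spec <- function(n_reflections = 200L,
                            cell = unit_cell(57.9, 84.8, 384.3),
                            d_min = 3.5,
                            multiplicity_range = c(5L, 160L),
                            mu_b = 0, sigma_b = 600,
                            scale_s = 6000, b_true = 30,
                            lognorm_sdlog = 0.5,
                            absent_fraction = 0.05,
                            n_frames = 500L,
                            mode = c("sfx", "synchrotron"),
                            seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(sigma_b > 0, scale_s > 0, n_reflections >= 2,
            multiplicity_range[1] >= 1, d_min > 0,
            absent_fraction >= 0, absent_fraction < 1)
  structure(list(n_reflections = as.integer(n_reflections), cell = cell,
                 d_min = d_min, multiplicity_range = as.integer(multiplicity_range),
                 mu_b = mu_b, sigma_b = sigma_b, scale_s = scale_s,
                 b_true = b_true, lognorm_sdlog = lognorm_sdlog,
                 absent_fraction = absent_fraction, n_frames = as.integer(n_frames),
                 mode = mode, seed = as.integer(seed)),
            class = "exg_sim_spec")
}

# random non-absent ASU indices within the resolution limit
sample_present_hkl <- function(n, cell, d_min) {
  hmax <- floor(cell$a / d_min); kmax <- floor(cell$b / d_min); lmax <- floor(cell$c / d_min)
  got <- character(0)
  out <- matrix(0L, 0, 3)
  while (nrow(out) < n) {
    h <- sample.int(hmax + 1L, 1L) - 1L
    k <- sample.int(kmax + 1L, 1L) - 1L
    l <- sample.int(lmax + 1L, 1L) - 1L
    if (h == 0L && k == 0L && l == 0L) next
    if (d_spacing(h, k, l, cell) < d_min) next
    if (is_systematically_absent(h, k, l)) next
    key <- paste(h, k, l)
    if (key %in% got) next
    got <- c(got, key)
    out <- rbind(out, c(h, k, l))
  }
  out
}

# axial odd-index reflections (the P2(1)2(1)2(1) absences) within the limit
sample_absent_hkl <- function(n, cell, d_min) {
  cand <- list()
  add <- function(h, k, l) cand[[length(cand) + 1L]] <<- c(h, k, l)
  for (h in seq(1, floor(cell$a / d_min), by = 2)) add(h, 0L, 0L)
  for (k in seq(1, floor(cell$b / d_min), by = 2)) add(0L, k, 0L)
  for (l in seq(1, floor(cell$c / d_min), by = 2)) add(0L, 0L, l)
  cand <- do.call(rbind, cand)
  cand[sample.int(nrow(cand), min(n, nrow(cand))), , drop = FALSE]
}

#' Generate a synthetic SFX or synchrotron observation dataset
#'
#' @param spec a \code{\link{simulation_spec}}.
#' @return list with elements \code{observations} (an
#'   \code{exg_observations} data.frame) and \code{truth} (data.frame with
#'   per-reflection \code{h,k,l,d,is_absent,multiplicity} and the ground
#'   truth \code{tau_true} (sfx) or \code{mu_true} (synchrotron);
#'   \code{b_true} as an attribute).
#' @export
simulate_dataset <- function(spec) {
  stopifnot(inherits(spec, "exg_sim_spec"))
  set.seed(spec$seed)
  n_absent <- round(spec$n_reflections * spec$absent_fraction)
  n_present <- spec$n_reflections - n_absent
  hkl <- sample_present_hkl(n_present, spec$cell, spec$d_min)
  if (n_absent > 0) hkl <- rbind(hkl, sample_absent_hkl(n_absent, spec$cell, spec$d_min))
  n <- nrow(hkl)
  d <- d_spacing(hkl[, 1], hkl[, 2], hkl[, 3], spec$cell)
  absent <- is_systematically_absent(hkl[, 1], hkl[, 2], hkl[, 3])
  mult <- sample(seq(spec$multiplicity_range[1], spec$multiplicity_range[2]), n, replace = TRUE)
  fmod <- exp(rnorm(n, 0, spec$lognorm_sdlog))
  wilson <- spec$scale_s * exp(-spec$b_true / (2 * d^2)) * fmod

  obs <- vector("list", n)
  for (i in seq_len(n)) {
    m <- mult[i]
    if (spec$mode == "sfx") {
      x <- rnorm(m, spec$mu_b, spec$sigma_b)
      if (!absent[i]) x <- x + rexp(m, rate = 1 / wilson[i])
    } else {
      mu_i <- wilson[i]
      sd_i <- 0.1 * abs(mu_i) + 0.2 * spec$sigma_b
      x <- rnorm(m, mu_i, sd_i)
    }
    obs[[i]] <- data.frame(
      frame_id = sprintf("img_%04d", sample.int(spec$n_frames, m, replace = TRUE)),
      h = hkl[i, 1], k = hkl[i, 2], l = hkl[i, 3],
      intensity = x,
      sigma = spec$sigma_b + 0.02 * abs(x),
      stringsAsFactors = FALSE
    )
  }
  observations <- do.call(rbind, obs)
  # scatter rows over frames (serial collection has no per-reflection order)
  observations <- observations[sample.int(nrow(observations)), , drop = FALSE]
  rownames(observations) <- NULL
  class(observations) <- c("exg_observations", "data.frame")

  truth <- data.frame(h = hkl[, 1], k = hkl[, 2], l = hkl[, 3],
                      d = d, is_absent = absent, multiplicity = mult)
  if (spec$mode == "sfx") {
    truth$tau_true <- ifelse(absent, 0, wilson)
  } else {
    truth$mu_true <- wilson
  }
  attr(truth, "b_true") <- spec$b_true
  list(observations = observations, truth = truth)
}

#' Write observations as a flat-dialect fixture
#'
#' Full-precision (\code{\%.17g}) output so
#' \code{\link{read_observation_table}} round-trips the values exactly.
#'
#' @param observations an \code{exg_observations} data.frame.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
export_fixture <- function(observations, path) {
  lines <- c("# frame_id h k l intensity sigma",
             sprintf("%s %d %d %d %.17g %.17g",
                     observations$frame_id, observations$h, observations$k,
                     observations$l, observations$intensity, observations$sigma))
  writeLines(lines, path)
  invisible(path)
}
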