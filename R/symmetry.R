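#' Orthorhombic unit cell
#'
#' Only orthorhombic cells (alpha = beta = gamma = 90 degrees) are supported;
#' anything else is an error.  Lengths in Angstrom.
#'
#' @param a,b,c cell edge lengths (Angstrom), > 0.
#' @param alpha,beta,gamma cell angles (degrees); must equal 90.
#' @return list of class \code{exg_cell}.
#' @export
unit_cell <- function(a, b, c, alpha = 90, beta = 90, gamma = 90) {
  stopifnot(is.numeric(a), is.numeric(b), is.numeric(c))
  if (!(a > 0 && b > 0 && c > 0)) stop("cell edges must be positive")
  if (any(abs(c(alpha, beta, gamma) - 90) > 1e-9)) {
    stop("only orthorhombic cells supported (alpha = beta = gamma = 90)")
  }
  structure(list(a = a, b = b, c = c, alpha = 90, beta = 90, gamma = 90),
            class = "exg_cell")
}

#' d-spacing of a reflection in an orthorhombic cell
#'
#' \eqn{d = (h^2/a^2 + k^2/b^2 + l^2/c^2)^{-1/2}}.  Vectorized over hkl.
#'
#' @param h,k,l Miller indices (integer vectors, recycled to common length).
#' @param cell a \code{\link{unit_cell}}.
#' @return d-spacing(s) in Angstrom.
#' @export
d_spacing <- function(h, k, l, cell) {
  stopifnot(inherits(cell, "exg_cell"))
  n <- max(length(h), length(k), length(l))
  h <- rep_len(h, n); k <- rep_len(k, n); l <- rep_len(l, n)
  if (any(h == 0 & k == 0 & l == 0)) stop("(0,0,0) has no d-spacing")
  1 / sqrt(h^2 / cell$a^2 + k^2 / cell$b^2 + l^2 / cell$c^2)
}

#' Map Miller indices to the asymmetric unit of Laue group mmm
#'
#' Point group 222 plus Friedel inversion makes the mmm orbit of (h,k,l) the
#' eight sign combinations; the canonical representative is
#' (|h|, |k|, |l|).  Idempotent.
#'
#' @param h,k,l Miller indices (vectors, recycled).
#' @return data.frame with columns \code{h,k,l} of ASU indices.
#' @export
map_to_asu <- function(h, k, l) {
  n <- max(length(h), length(k), length(l))
  h <- rep_len(h, n); k <- rep_len(k, n); l <- rep_len(l, n)
  if (any(h == 0 & k == 0 & l == 0)) stop("(0,0,0) is not a reflection")
  data.frame(h = abs(as.integer(h)), k = abs(as.integer(k)), l = abs(as.integer(l)))
}

#' Systematic-absence test for space group P2(1)2(1)2(1)
#'
#' The three 2\eqn{_1} screw axes impose the reflection conditions h00: h = 2n,
#' 0k0: k = 2n, 00l: l = 2n.  A reflection is systematically absent iff it is
#' axial with an odd index.  Vectorized.
#'
#' @param h,k,l Miller indices (vectors, recycled).
#' @return logical vector.
#' @export
is_systematically_absent <- function(h, k, l) {
  n <- max(length(h), length(k), length(l))
  h <- rep_len(h, n); k <- rep_len(k, n); l <- rep_len(l, n)
  if (any(h == 0 & k == 0 & l == 0)) stop("(0,0,0) is not a reflection")
  (k == 0 & l == 0 & h %% 2 != 0) |
  (h == 0 & l == 0 & k %% 2 != 0) |
  (h == 0 & k == 0 & l %% 2 != 0)
}

#' Group observations by ASU index
#'
#' Maps every observation into the asymmetric unit (Friedel pairs merged,
#' anomalous signal ignored), and collects per unique index the ordered
#' intensities, d-spacing, q = 1/d^2 and the absence flag.
#'
#' @param observations an \code{exg_observations} data.frame
#'   (see \code{\link{read_observation_table}}).
#' @param cell a \code{\link{unit_cell}}.
#' @param space_group space-group symbol; only \code{"P212121"} is supported.
#' @return list of class \code{exg_group_list}; each element has fields
#'   \code{h,k,l} (ASU), \code{d_spacing}, \code{q}, \code{is_absent},
#'   \code{intensities}, \code{multiplicity}.
#' @export
group_observations <- function(observations, cell, space_group = "P212121") {
  if (!identical(space_group, "P212121")) {
    stop(sprintf("unsupported space group '%s': only P212121 is implemented", space_group))
  }
  stopifnot(is.data.frame(observations))
  if (nrow(observations) == 0L) stop("empty dataset: no observations to group")
  asu <- map_to_asu(observations$h, observations$k, observations$l)
  key <- paste(asu$h, asu$k, asu$l)
  # preserve input order within groups; order groups by first appearance
  idx <- split(seq_len(nrow(observations)), factor(key, levels = unique(key)))
  groups <- lapply(names(idx), function(kk) {
    i <- idx[[kk]]
    hkl <- as.integer(strsplit(kk, " ", fixed = TRUE)[[1]])
    d <- d_spacing(hkl[1], hkl[2], hkl[3], cell)
    list(h = hkl[1], k = hkl[2], l = hkl[3],
         d_spacing = d, q = 1 / d^2,
         is_absent = is_systematically_absent(hkl[1], hkl[2], hkl[3]),
         intensities = observations$intensity[i],
         multiplicity = length(i))
  })
  stopifnot(sum(vapply(groups, `[[`, integer(1), "multiplicity")) == nrow(observations))
  structure(groups, class = "exg_group_list")
}
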