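#' Read an unmerged observation table
#'
#' Parses a list of unmerged Bragg observations in one of two plain-text
#' dialects:
#' \describe{
#'   \item{\code{"flat"}}{whitespace- or tab-separated columns
#'     \code{frame_id h k l I [sigma]}; lines starting with \code{#} are
#'     comments.}
#'   \item{\code{"stream-lite"}}{per-frame blocks delimited by literal lines
#'     \code{BEGIN_CHUNK <frame_id>} and \code{END_CHUNK}, each containing
#'     rows \code{h k l I [sigma]}.  A minimal stand-in for a full stream
#'     grammar, which is out of scope.}
#' }
#' Malformed lines (non-integer Miller indices, non-numeric intensity) are
#' skipped and counted, not fatal; the count is reported via \code{message()}.
#'
#' @param source path to a file, or a character vector of lines.
#' @param dialect \code{"flat"} (default) or \code{"stream-lite"}.
#' @return A data.frame of class \code{exg_observations} with columns
#'   \code{frame_id} (character), \code{h}, \code{k}, \code{l} (integer),
#'   \code{intensity} (double) and \code{sigma} (double, \code{NA} when the
#'   column is absent; never imputed).  Attribute \code{n_skipped} carries the
#'   malformed-line count.
#' @export
read_observation_table <- function(source, dialect = c("flat", "stream-lite")) {
  dialect <- match.arg(dialect)
  lines <- if (length(source) == 1L && !grepl("\n", source) && file.exists(source)) {
    readLines(source, warn = FALSE)
  } else if (is.character(source)) {
    unlist(strsplit(source, "\n", fixed = TRUE))
  } else {
    stop("unreadable source: expected a file path or character lines")
  }

  int_re <- "^[+-]?[0-9]+$"
  is_num <- function(s) !is.na(suppressWarnings(as.numeric(s)))

  rows <- list()
  n_skipped <- 0L
  push <- function(frame_id, tok) {
    # tok = h k l I [sigma]
    if (length(tok) < 4L || length(tok) > 5L ||
        !all(grepl(int_re, tok[1:3])) || !is_num(tok[4]) ||
        (length(tok) == 5L && !is_num(tok[5]))) {
      return(FALSE)
    }
    h <- as.integer(tok[1]); k <- as.integer(tok[2]); l <- as.integer(tok[3])
    if (h == 0L && k == 0L && l == 0L) return(FALSE)
    inten <- as.numeric(tok[4])
    sig <- if (length(tok) == 5L) as.numeric(tok[5]) else NA_real_
    if (!is.finite(inten) || (!is.na(sig) && (!is.finite(sig) || sig < 0))) return(FALSE)
    rows[[length(rows) + 1L]] <<- list(frame_id, h, k, l, inten, sig)
    TRUE
  }

  if (dialect == "flat") {
    for (ln in lines) {
      ln <- trimws(ln)
      if (ln == "" || startsWith(ln, "#")) next
      tok <- strsplit(ln, "[ \t]+")[[1]]
      if (length(tok) < 5L || !push(tok[1], tok[-1])) n_skipped <- n_skipped + 1L
    }
  } else {
    frame <- NULL
    for (ln in lines) {
      ln <- trimws(ln)
      if (ln == "" || startsWith(ln, "#")) next
      if (startsWith(ln, "BEGIN_CHUNK")) {
        tok <- strsplit(ln, "[ \t]+")[[1]]
        frame <- if (length(tok) >= 2L) tok[2] else sprintf("chunk_%06d", length(rows))
      } else if (ln == "END_CHUNK") {
        frame <- NULL
      } else if (!is.null(frame)) {
        if (!push(frame, strsplit(ln, "[ \t]+")[[1]])) n_skipped <- n_skipped + 1L
      } else {
        n_skipped <- n_skipped + 1L
      }
    }
  }

  if (length(rows) == 0L) stop("empty dataset: no valid observations parsed")
  if (n_skipped > 0L) message(sprintf("read_observation_table: skipped %d malformed line(s)", n_skipped))

  obs <- data.frame(
    frame_id  = vapply(rows, `[[`, character(1), 1L),
    h         = vapply(rows, `[[`, integer(1), 2L),
    k         = vapply(rows, `[[`, integer(1), 3L),
    l         = vapply(rows, `[[`, integer(1), 4L),
    intensity = vapply(rows, `[[`, numeric(1), 5L),
    sigma     = vapply(rows, `[[`, numeric(1), 6L),
    stringsAsFactors = FALSE
  )
  attr(obs, "n_skipped") <- n_skipped
  class(obs) <- c("exg_observations", "data.frame")
  obs
}

#' Write a merged reflection file
#'
#' Writes one row per unique reflection, \code{h k l I sigma multiplicity},
#' sorted ascending by (h, k, l), after header comment lines carrying the
#' unit cell, space group and column legend.  Values are printed with 6
#' significant digits; \code{\link{read_merged}} round-trips them at that
#' precision.
#'
#' @param records data.frame with columns \code{h,k,l,intensity,sigma,multiplicity}.
#' @param cell a \code{\link{unit_cell}}.
#' @param destination output file path.
#' @param space_group space-group symbol written to the header.
#' @return \code{destination}, invisibly.
#' @export
write_merged <- function(records, cell, destination, space_group = "P212121") {
  stopifnot(is.data.frame(records),
            all(c("h", "k", "l", "intensity", "sigma", "multiplicity") %in% names(records)))
  key <- paste(records$h, records$k, records$l)
  if (anyDuplicated(key)) {
    dup <- key[duplicated(key)][1]
    stop(sprintf("duplicate ASU index in merged records: (%s)", gsub(" ", ",", dup)))
  }
  if (any(records$sigma < 0, na.rm = TRUE)) stop("negative sigma in merged records")
  if (any(records$multiplicity < 1)) stop("non-positive multiplicity in merged records")
  ord <- order(records$h, records$k, records$l)
  records <- records[ord, , drop = FALSE]
  hdr <- c(
    sprintf("# unit_cell %.6g %.6g %.6g %.6g %.6g %.6g",
            cell$a, cell$b, cell$c, cell$alpha, cell$beta, cell$gamma),
    sprintf("# space_group %s", space_group),
    "# h k l intensity sigma multiplicity"
  )
  body <- sprintf("%d %d %d %s %s %d",
                  records$h, records$k, records$l,
                  formatC(records$intensity, digits = 6, format = "g"),
                  formatC(records$sigma, digits = 6, format = "g"),
                  records$multiplicity)
  writeLines(c(hdr, body), destination)
  invisible(destination)
}

#' Read a merged reflection file written by [write_merged()]
#'
#' @param path file path.
#' @return data.frame with columns \code{h,k,l,intensity,sigma,multiplicity};
#'   the parsed unit cell is attached as attribute \code{cell} and the space
#'   group as attribute \code{space_group}.
#' @export
read_merged <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- lines[startsWith(lines, "#")]
  body <- lines[!startsWith(lines, "#") & nzchar(trimws(lines))]
  if (length(body) == 0L) stop("empty dataset: no merged records in file")
  tok <- strsplit(trimws(body), "[ \t]+")
  out <- data.frame(
    h = vapply(tok, function(t) as.integer(t[1]), integer(1)),
    k = vapply(tok, function(t) as.integer(t[2]), integer(1)),
    l = vapply(tok, function(t) as.integer(t[3]), integer(1)),
    intensity = vapply(tok, function(t) as.numeric(t[4]), numeric(1)),
    sigma = vapply(tok, function(t) as.numeric(t[5]), numeric(1)),
    multiplicity = vapply(tok, function(t) as.integer(t[6]), integer(1))
  )
  cell_ln <- hdr[grepl("^# unit_cell", hdr)]
  if (length(cell_ln)) {
    v <- as.numeric(strsplit(trimws(sub("^# unit_cell", "", cell_ln[1])), "[ \t]+")[[1]])
    attr(out, "cell") <- unit_cell(v[1], v[2], v[3], v[4], v[5], v[6])
  }
  sg_ln <- hdr[grepl("^# space_group", hdr)]
  if (length(sg_ln)) attr(out, "space_group") <- trimws(sub("^# space_group", "", sg_ln[1]))
  out
}
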