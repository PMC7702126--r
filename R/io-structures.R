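#' Read and write XYZ coordinate files
#'
#' Standard XYZ: per frame, an atom-count line, a comment line, then one
#' "element x y z" line per atom (Angstrom). Multi-frame files are read as a
#' [Trajectory-class]; single-frame files as a [Conformer-class]. Atom labels
#' are regenerated as element symbol plus a per-element counter (C1, C2, ...,
#' H1, ...), identically across frames.
#'
#' @param path file path.
#' @return a [Conformer-class] or [Trajectory-class].
#' @export
readXYZ <- function(path) {
  if (!file.exists(path)) .err("invalid_input", "file not found: %s", path)
  lines <- readLines(path)
  lines <- lines[seq_len(max(which(nzchar(trimws(lines))), 0L))]
  frames <- list()
  i <- 1L
  while (i <= length(lines)) {
    nat <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(nat) || nat < 1L)
      .err("format", "line %d: expected an atom count", i)
    if (i + 1L + nat > length(lines))
      .err("format", "truncated frame starting at line %d", i)
    comment <- lines[i + 1L]
    toks <- strsplit(trimws(lines[(i + 2L):(i + 1L + nat)]), "\\s+")
    el <- vapply(toks, `[`, character(1), 1L)
    xyz <- t(vapply(toks, function(t) as.numeric(t[2:4]), numeric(3)))
    cnt <- stats::ave(seq_along(el), el, FUN = seq_along)
    energy <- NA_real_
    em <- regmatches(comment,
                     regexpr("energy\\s*=\\s*(-?[0-9.eE+-]+)", comment))
    if (length(em) == 1L)
      energy <- as.numeric(sub("energy\\s*=\\s*", "", em))
    frames[[length(frames) + 1L]] <-
      conformer(paste0(el, cnt), elements = el, coords = xyz,
                name = sprintf("%s#%d", basename(path), length(frames) + 1L),
                energy = energy)
    i <- i + 2L + nat
  }
  if (length(frames) == 1L) frames[[1L]] else trajectory(frames)
}

#' @rdname readXYZ
#' @param x a [Conformer-class] or [Trajectory-class] to write.
#' @param comment comment-line text (recycled over frames).
#' @export
writeXYZ <- function(x, path, comment = "") {
  fr <- if (is(x, "Trajectory")) x@frames else list(x)
  comment <- rep_len(comment, length(fr))
  con <- file(path, "w")
  on.exit(close(con))
  for (k in seq_along(fr)) {
    cf <- fr[[k]]
    cm <- comment[k]
    if (!is.na(cf@energy) && !grepl("energy", cm))
      cm <- trimws(sprintf("%s energy = %.6f", cm, cf@energy))
    writeLines(c(as.character(length(cf@labels)), cm), con)
    writeLines(sprintf("%-3s %14.8f %14.8f %14.8f", cf@elements,
                       cf@coords[, 1], cf@coords[, 2], cf@coords[, 3]), con)
  }
  invisible(path)
}

#' Read a single conformer from an SDF/MOL (V2000) file
#'
#' Parsing is delegated to \pkg{ChemmineR}; only the first molecule is
#' returned. Atom labels follow the SDF atom order as element plus index.
#'
#' @param path file path.
#' @return a [Conformer-class].
#' @export
readSDF <- function(path) {
  if (!file.exists(path)) .err("invalid_input", "file not found: %s", path)
  sdfs <- ChemmineR::read.SDFset(path)
  ab <- ChemmineR::atomblock(sdfs[[1L]])
  el <- sub("_.*$", "", rownames(ab))
  cnt <- stats::ave(seq_along(el), el, FUN = seq_along)
  conformer(paste0(el, cnt), elements = el, coords = ab[, 1:3, drop = FALSE],
            name = basename(path))
}
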