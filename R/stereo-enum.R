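#' Stereocenters of the quinolizidine scaffold, in descriptor-string order
#' @return character vector of the seven center labels.
#' @examples stereoCenters()
#' @export
stereoCenters <- function() c("C2", "C3", "C4", "C5", "C6", "N8", "C23")

#' Enumerate candidate relative configurations
#'
#' Generates all R/S descriptor strings over the seven stereocenters
#' (C2 C3 C4 C5 C6 N8 C23) with a subset of centers held fixed. Fixing one
#' center excludes enantiomers (RDCs cannot distinguish mirror images); the
#' standard candidate set fixes C2 = R and, on steric grounds of the fused
#' lactone ring, C4 = S, giving 2^5 = 32 relative configurations.
#'
#' @param fixed named character vector, e.g. \code{c(C2 = "R", C4 = "S")}.
#' @param free character vector of centers to enumerate; defaults to all
#'   centers not named in \code{fixed}. A center may not appear in both.
#' @return character vector of descriptor strings of length 7, in
#'   deterministic lexicographic order.
#' @examples
#' cfgs <- enumerateConfigs(fixed = c(C2 = "R", C4 = "S"))
#' length(cfgs)        # 32
#' "RRSSSSR" %in% cfgs # TRUE
#' @export
enumerateConfigs <- function(fixed = c(C2 = "R", C4 = "S"), free = NULL) {
  centers <- stereoCenters()
  fixed <- if (length(fixed)) vapply(fixed, as.character, character(1)) else
    character(0)
  if (!all(names(fixed) %in% centers) || !all(fixed %in% c("R", "S")))
    .err("validation", "fixed must map known centers to \"R\"/\"S\"")
  if (is.null(free)) free <- setdiff(centers, names(fixed))
  if (!all(free %in% centers))
    .err("validation", "unknown center(s) in free: %s",
         paste(setdiff(free, centers), collapse = ", "))
  clash <- intersect(names(fixed), free)
  if (length(clash) > 0L)
    .err("conflict", "center(s) both fixed and free: %s",
         paste(clash, collapse = ", "))
  base <- setNames(rep(NA_character_, length(centers)), centers)
  base[names(fixed)] <- fixed
  if (length(free) == 0L) {
    if (anyNA(base))
      .err("validation", "centers neither fixed nor free: %s",
           paste(centers[is.na(base)], collapse = ", "))
    return(paste(base, collapse = ""))
  }
  combos <- expand.grid(rep(list(c("R", "S")), length(free)),
                        stringsAsFactors = FALSE)
  out <- vapply(seq_len(nrow(combos)), function(i) {
    d <- base
    d[free] <- unlist(combos[i, ], use.names = FALSE)
    paste(d, collapse = "")
  }, character(1))
  sort(unique(out))
}

#' Match a descriptor string to its running number
#'
#' Looks a 7-letter R/S descriptor string up in the embedded candidate table
#' ([rd1Configurations()]). Matching is by string, never by enumeration
#' position: the published running numbers are not in lexicographic order.
#'
#' @param descriptor character string of 7 R/S letters.
#' @return integer running number, or \code{NA_integer_} if not listed.
#' @examples
#' matchConfigId("RRSSSSR")  # 11
#' @export
matchConfigId <- function(descriptor) {
  if (!is.character(descriptor) || length(descriptor) != 1L ||
      nchar(descriptor) != 7L || grepl("[^RS]", descriptor))
    .err("validation", "descriptor must be 7 characters of R/S")
  tab <- rd1Configurations()
  hit <- match(descriptor, tab$descriptor)
  if (is.na(hit)) NA_integer_ else tab$id[hit]
}
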