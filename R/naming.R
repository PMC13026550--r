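#' Name an intron after its host gene and insertion site
#'
#' Introns (and intron families) are named `<gene>-<site>`: the host gene
#' followed by the 1-based reference-gene position after which the intron is
#' inserted, e.g. `cox1-686` lies between positions 686 and 687 of `cox1`.
#'
#' @param host_gene Host gene name (nonempty string).
#' @param site Positive integer insertion site on the reference gene.
#' @return The intron name, a string.
#' @examples
#' name_intron("cox1", 686)
#' name_intron("infA", 62)
#' @seealso [parse_intron_name()]
#' @export
name_intron <- function(host_gene, site) {
  stopifnot(is.character(host_gene), nzchar(host_gene))
  site <- as.integer(site)
  if (is.na(site) || site <= 0L) {
    stop("insertion site must be a positive integer", call. = FALSE)
  }
  paste0(host_gene, "-", site)
}

#' Parse an intron name into host gene and insertion site
#'
#' Inverse of [name_intron()]. Gene names may themselves contain hyphens;
#' the site is taken after the *last* hyphen, which must be followed by
#' digits only.
#'
#' @param id Intron name of the form `<gene>-<site>`.
#' @return A list with elements `gene` (string) and `site` (integer).
#' @examples
#' parse_intron_name("nad5-1057")
#' @export
parse_intron_name <- function(id) {
  stopifnot(is.character(id), length(id) == 1L)
  m <- regmatches(id, regexec("^(.+)-([0-9]+)$", id))[[1L]]
  if (length(m) != 3L) {
    stop("malformed intron name (expected '<gene>-<site>'): ", id, call. = FALSE)
  }
  site <- as.integer(m[3L])
  if (site <= 0L) stop("malformed intron name (site must be >= 1): ", id, call. = FALSE)
  list(gene = m[2L], site = site)
}
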