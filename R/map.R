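#' Linkage map objects
#'
#' A linkage map is a data frame with columns `chrom` (character),
#' `marker` (character, unique) and `pos_cM` (numeric, strictly increasing
#' within each chromosome, all >= 0), carrying class `magic_map`.
#'
#' @param chrom character vector of chromosome names.
#' @param marker character vector of marker names (unique).
#' @param pos_cM numeric vector of positions in centimorgans.
#' @return A `magic_map` data frame.
#' @export
magic_map <- function(chrom, marker, pos_cM) {
  map <- data.frame(chrom = as.character(chrom),
                    marker = as.character(marker),
                    pos_cM = as.numeric(pos_cM),
                    stringsAsFactors = FALSE)
  validate_magic_map(map)
}

validate_magic_map <- function(map, sort = FALSE) {
  stopifnot(all(c("chrom", "marker", "pos_cM") %in% names(map)))
  if (anyNA(map$pos_cM) || any(map$pos_cM < 0))
    stop("marker positions must be non-negative and non-missing")
  if (anyDuplicated(map$marker))
    stop("duplicated marker names in map")
  # keep chromosomes in order of first appearance
  map$chrom <- factor(map$chrom, levels = unique(map$chrom))
  if (sort) {
    o <- order(map$chrom, map$pos_cM)
    if (is.unsorted(o)) warning("map positions were not sorted; sorting within chromosomes")
    map <- map[o, , drop = FALSE]
  }
  for (ch in levels(map$chrom)) {
    p <- map$pos_cM[map$chrom == ch]
    if (length(p) < 2L)
      stop("chromosome ", ch, " has fewer than 2 markers")
    if (any(diff(p) <= 0))
      stop("marker positions not strictly increasing on chromosome ", ch)
  }
  map$chrom <- as.character(map$chrom)
  rownames(map) <- NULL
  class(map) <- c("magic_map", "data.frame")
  map
}

#' Simulate an equally spaced linkage map
#'
#' @param n_chrom number of chromosomes.
#' @param length_cM chromosome length in centimorgans.
#' @param n_markers number of equally spaced markers per chromosome
#'   (>= 2); markers span `[0, length_cM]`.
#' @return A [magic_map()] with chromosomes `C1..Cn` and markers
#'   `C<k>M<j>`.
#' @examples
#' map <- sim_linkage_map(7, 300, 201)  # 1.5 cM spacing
#' @export
sim_linkage_map <- function(n_chrom, length_cM, n_markers) {
  if (n_chrom < 1 || length_cM <= 0 || n_markers < 2)
    stop("need n_chrom >= 1, length_cM > 0 and n_markers >= 2")
  chrom <- rep(paste0("C", seq_len(n_chrom)), each = n_markers)
  pos <- rep(seq(0, length_cM, length.out = n_markers), n_chrom)
  marker <- paste0(chrom, "M", rep(seq_len(n_markers), n_chrom))
  magic_map(chrom, marker, pos)
}

map_chroms <- function(map) unique(map$chrom)

map_split <- function(map) split(seq_len(nrow(map)), factor(map$chrom, levels = map_chroms(map)))

#' @export
print.magic_map <- function(x, ...) {
  ch <- map_chroms(x)
  cat("Linkage map:", length(ch), "chromosome(s),", nrow(x), "markers\n")
  for (cc in ch) {
    p <- x$pos_cM[x$chrom == cc]
    cat(sprintf("  %s: %d markers, %.1f cM\n", cc, length(p), max(p) - min(p)))
  }
  invisible(x)
}
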