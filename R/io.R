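## CSV readers and writers for the package's interchange formats.
## All files are plain UTF-8 CSV with headers.

#' Read and write linkage maps
#'
#' Map CSV columns: `chrom`, `marker`, `pos_cM`.  Rows out of position
#' order are sorted within chromosome with a warning.
#'
#' @param file path.
#' @return [read_linkage_map()] returns a [magic_map()].
#' @export
read_linkage_map <- function(file) {
  d <- utils::read.csv(file, stringsAsFactors = FALSE)
  need <- c("chrom", "marker", "pos_cM")
  if (!all(need %in% names(d)))
    stop("map file must have columns ", paste(need, collapse = ", "),
         "; missing: ", paste(setdiff(need, names(d)), collapse = ", "))
  validate_magic_map(d[need], sort = TRUE)
}

#' @rdname read_linkage_map
#' @param map a [magic_map()].
#' @export
write_linkage_map <- function(map, file) {
  utils::write.csv(as.data.frame(unclass(map))[c("chrom", "marker", "pos_cM")],
                   file, row.names = FALSE)
  invisible(file)
}

#' Read and write long-format phenotypes
#'
#' Phenotype CSV columns: `line`, `trait`, `rep`, `value`.
#'
#' @param file path.
#' @export
read_phenotypes <- function(file) {
  d <- utils::read.csv(file, stringsAsFactors = FALSE)
  need <- c("line", "trait", "rep", "value")
  if (!all(need %in% names(d)))
    stop("phenotype file must have columns ", paste(need, collapse = ", "),
         "; missing: ", paste(setdiff(need, names(d)), collapse = ", "))
  d <- d[need]
  if (!is.numeric(d$value)) stop("phenotype column value must be numeric")
  structure(d, class = c("magic_pheno", "data.frame"))
}

#' @rdname read_phenotypes
#' @param pheno phenotype data frame.
#' @export
write_phenotypes <- function(pheno, file) {
  utils::write.csv(as.data.frame(pheno)[c("line", "trait", "rep", "value")],
                   file, row.names = FALSE)
  invisible(file)
}

#' Write simulated founder origins
#'
#' Long CSV with columns `line`, `chrom`, `marker`, `founder`.
#'
#' @param pop a `magic_pop`.
#' @param file path.
#' @export
write_founder_origins <- function(pop, file) {
  map <- pop$map
  d <- data.frame(line = rep(rownames(pop$origins), times = nrow(map)),
                  chrom = rep(map$chrom, each = nrow(pop$origins)),
                  marker = rep(map$marker, each = nrow(pop$origins)),
                  founder = as.vector(pop$origins),
                  stringsAsFactors = FALSE)
  utils::write.csv(d, file, row.names = FALSE)
  invisible(file)
}

#' Read and write founder-probability matrices
#'
#' Probability CSV: a `line` column plus one column per
#' chromosome/item/founder named `CHR.ITEM.Ff`.  Every founder block
#' row must sum to 1 (tolerance 1e-6).
#'
#' @param file path.
#' @param map optional [magic_map()] used to attach interval positions.
#' @param mode `"interval"` or `"marker"`.
#' @export
read_founder_probs <- function(file, map = NULL,
                               mode = c("interval", "marker")) {
  mode <- match.arg(mode)
  d <- utils::read.csv(file, stringsAsFactors = FALSE, check.names = FALSE)
  if (names(d)[1] != "line") stop("first column must be 'line'")
  lines <- as.character(d[[1]])
  prob <- as.matrix(d[-1])
  parts <- regmatches(colnames(prob),
                      regexec("^(.+)\\.([0-9]+)\\.F([0-9]+)$", colnames(prob)))
  bad <- vapply(parts, length, 0L) != 4L
  if (any(bad))
    stop("malformed probability column name(s): ",
         paste(utils::head(colnames(prob)[bad], 3), collapse = ", "))
  index <- data.frame(
    chrom = vapply(parts, `[`, "", 2),
    item = as.integer(vapply(parts, `[`, "", 3)),
    founder = as.integer(vapply(parts, `[`, "", 4)),
    stringsAsFactors = FALSE)
  n_f <- max(index$founder)
  ## row sums within each block
  for (b in seq_len(nrow(index) / n_f)) {
    cols <- (b - 1L) * n_f + seq_len(n_f)
    rs <- rowSums(prob[, cols, drop = FALSE])
    if (any(abs(rs - 1) > 1e-6))
      stop("probability rows not summing to 1 in block ",
           index$chrom[cols[1]], ".", index$item[cols[1]],
           " (line ", lines[which.max(abs(rs - 1))], ")")
  }
  if (!is.null(map)) {
    map <- validate_magic_map(map)
    for (cc in unique(index$chrom)) {
      pos <- map$pos_cM[map$chrom == cc]
      sel <- index$chrom == cc
      if (mode == "interval") {
        index$left_cM[sel] <- pos[index$item[sel]]
        index$right_cM[sel] <- pos[index$item[sel] + 1L]
        index$pos_cM[sel] <- (index$left_cM[sel] + index$right_cM[sel]) / 2
      } else {
        index$pos_cM[sel] <- pos[index$item[sel]]
      }
    }
  } else {
    index$pos_cM <- NA_real_
  }
  rownames(prob) <- lines
  new_founder_probs(prob, index, map, mode, n_f)
}

#' @rdname read_founder_probs
#' @param fp a `founder_probs`.
#' @export
write_founder_probs <- function(fp, file) {
  d <- data.frame(line = rownames(fp$prob), stringsAsFactors = FALSE)
  d <- cbind(d, as.data.frame(fp$prob, check.names = FALSE))
  utils::write.csv(d, file, row.names = FALSE)
  invisible(file)
}
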