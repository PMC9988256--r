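#' @useDynLib myoatlas, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats anova aov as.dist as.formula coef cor cor.test cutree
#'   hclust lm mad median model.matrix p.adjust pf prcomp ptukey pt qnorm
#'   quantile rbinom resid rgamma rlnorm rmultinom rnbinom rnorm rpois runif
#'   sd setNames var vcov complete.cases
#' @importFrom utils head read.delim write.table read.csv write.csv
#' @importFrom grDevices png dev.off
#' @importFrom graphics boxplot
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a per-stage seed from a global seed
#'
#' Stage seeds are `seed * 8 + offset`, kept below 2^31 so they remain valid
#' R integers. Used by [run_pipeline()] so that toggling stages does not
#' perturb the random streams of other stages.
#'
#' @param seed integer global seed.
#' @param offset integer stage offset (0-7).
#' @return integer seed.
#' @export
stage_seed <- function(seed, offset) {
  s <- (as.numeric(seed) * 8 + offset) %% 2147483647
  as.integer(s)
}

#' Read gene sets in GMT format
#'
#' Each line: set name, description, then tab-separated gene identifiers.
#'
#' @param path file path.
#' @return named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    f[-(1:2)]
  })
  names(sets) <- vapply(lines, function(l)
    strsplit(l, "\t", fixed = TRUE)[[1]][1], character(1))
  sets
}

#' Write gene sets in GMT format
#'
#' @param sets named list of character vectors.
#' @param path file path.
#' @param description optional per-set description (recycled).
#' @export
write_gmt <- function(sets, path, description = "na") {
  stopifnot(is.list(sets), !is.null(names(sets)))
  description <- rep_len(description, length(sets))
  lines <- vapply(seq_along(sets), function(i)
    paste(c(names(sets)[i], description[i], sets[[i]]), collapse = "\t"),
    character(1))
  writeLines(lines, path)
}

#' Write a numeric matrix as TSV with row identifiers
#' @param m matrix with rownames.
#' @param path file path.
#' @param id_col name of the first (identifier) column.
#' @export
write_matrix_tsv <- function(m, path, id_col = "id") {
  df <- data.frame(rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df)[1] <- id_col
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a numeric matrix from TSV (first column = row identifiers)
#' @param path file path.
#' @return numeric matrix with rownames.
#' @export
read_matrix_tsv <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

## elementwise quantile across a list of equally sized matrices,
## computed on a pair x matrix layout via the compiled row-quantile kernel
.elementwise_quantile <- function(mats, q) {
  stacked <- vapply(mats, as.numeric, numeric(length(mats[[1]])))
  vals <- row_quantile_cpp(stacked, q)
  matrix(vals, nrow = nrow(mats[[1]]), dimnames = dimnames(mats[[1]]))
}

.assert_count <- function(x, name, min = 1) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < min || x != floor(x))
    stop(sprintf("`%s` must be an integer >= %d", name, min), call. = FALSE)
  as.integer(x)
}
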