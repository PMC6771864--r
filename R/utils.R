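#' Parse a genomic region string
#'
#' Accepts `"chr19:44400000-46500000"` (1-based, closed on both ends) or a
#' list/data.frame with `chrom`, `start`, `end`.
#'
#' @param region character scalar or list with chrom/start/end.
#' @return list with `chrom` (character), `start`, `end` (integer, 1-based
#'   closed).
#' @export
parse_region <- function(region) {
  if (is.list(region)) {
    out <- list(chrom = as.character(region$chrom),
                start = as.numeric(region$start),
                end = as.numeric(region$end))
  } else if (is.character(region) && length(region) == 1L) {
    m <- regmatches(region, regexec("^([^:]+):([0-9,]+)-([0-9,]+)$", region))[[1]]
    if (length(m) != 4L) stop("cannot parse region string: ", region)
    strip <- function(x) as.numeric(gsub(",", "", x, fixed = TRUE))
    out <- list(chrom = m[2], start = strip(m[3]), end = strip(m[4]))
  } else {
    stop("region must be a string 'chr:start-end' or a list(chrom, start, end)")
  }
  if (is.na(out$start) || is.na(out$end) || out$start > out$end)
    stop("invalid region: start must be <= end")
  out
}

# APOE region as printed coordinates 19:44,400-46,500 kb -> 44.4-46.5 Mb
#' Default APOE region (chr19:44,400,000-46,500,000, 1-based closed)
#' @export
apoe_region_default <- function() {
  list(chrom = "19", start = 44400000, end = 46500000)
}

#' Rank-based AUC (Wilcoxon statistic)
#'
#' Probability that a randomly drawn case has a higher score than a randomly
#' drawn control, with ties counted one half.
#'
#' @param score numeric vector of scores.
#' @param outcome binary 0/1 (or logical) vector; 1 = case.
#' @return AUC in \[0, 1\].
#' @export
auc_rank <- function(score, outcome) {
  outcome <- as.integer(outcome)
  stopifnot(length(score) == length(outcome), all(outcome %in% c(0L, 1L)))
  n1 <- sum(outcome == 1L)
  n0 <- sum(outcome == 0L)
  if (n1 == 0L || n0 == 0L) stop("AUC needs both cases and controls")
  r <- rank(score)
  (sum(r[outcome == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# internal: stop unless all names present in a data frame
need_cols <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss))
    stop(what, " is missing required column(s): ", paste(miss, collapse = ", "))
  invisible(TRUE)
}
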