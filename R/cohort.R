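# Turns longitudinal diagnosis records and amyloid-PET SUVR values into the
# four case/control framings of the analysis: AD vs controls, MCI vs
# controls, amyloid-positive vs -negative, and MCI->AD converters vs stable
# MCI among amyloid-positive baseline-MCI subjects.

#' Classify each subject's diagnosis trajectory into an analysis label
#'
#' Labels follow the clinical-usage convention of the longitudinal cohort:
#' stable CN -> CONTROL; stable MCI -> MCI; stable AD -> AD; CN->MCI and
#' MCI->CN reversions -> EXCLUDE; MCI->AD -> MCI with `converter = TRUE`;
#' AD->MCI -> MCI. Non-monotone paths are resolved by the (first, last)
#' diagnosis pair. The converter flag is true whenever the baseline
#' diagnosis is MCI and any later visit is AD. With
#' `last_diagnosis_wins = TRUE` the label is instead the last visit's
#' diagnosis (so MCI->AD converters are labelled AD); the default keeps
#' converters in the MCI arm, and the discrepancy between the two
#' conventions is surfaced as a one-time warning.
#'
#' @param visits visit-level data.frame (IID, VISIT, DX, ...).
#' @param last_diagnosis_wins use the last diagnosis as the label.
#' @return data.frame: IID, label (CONTROL/MCI/AD/EXCLUDE), baseline_dx,
#'   final_dx, converter.
#' @export
classify_trajectory <- function(visits, last_diagnosis_wins = FALSE) {
  need_cols(visits, c("IID", "VISIT", "DX"), "visit table")
  if (!nrow(visits)) stop("empty visit list")
  bad <- setdiff(unique(visits$DX), c("CN", "MCI", "AD"))
  if (length(bad)) stop("unknown DX code(s): ", paste(bad, collapse = ", "))
  visits <- visits[order(visits$IID, visits$VISIT), , drop = FALSE]
  by_subj <- split(visits$DX, visits$IID)
  first <- vapply(by_subj, function(d) d[1L], character(1))
  last <- vapply(by_subj, function(d) d[length(d)], character(1))
  conv <- vapply(by_subj, function(d)
    d[1L] == "MCI" && any(d[-1L] == "AD"), logical(1))
  pair <- paste(first, last, sep = ">")
  label <- if (last_diagnosis_wins) last else {
    map <- c("CN>CN" = "CONTROL", "MCI>MCI" = "MCI", "AD>AD" = "AD",
             "CN>MCI" = "EXCLUDE", "MCI>CN" = "EXCLUDE", "MCI>AD" = "MCI",
             "AD>MCI" = "MCI", "CN>AD" = "AD", "AD>CN" = "EXCLUDE")
    unname(map[pair])
  }
  if (last_diagnosis_wins) label[label == "CN"] <- "CONTROL"
  if (!last_diagnosis_wins && any(pair == "MCI>AD"))
    warning("MCI->AD converters are labelled MCI (cohort-usage convention); ",
            "set last_diagnosis_wins = TRUE for last-diagnosis labels",
            call. = FALSE)
  data.frame(IID = names(by_subj), label = label, baseline_dx = unname(first),
             final_dx = unname(last), converter = unname(conv),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Assign amyloid status from the latest SUVR
#'
#' A subject is POSITIVE when the latest available SUVR is `>= threshold`
#' (AV45 cutoff 1.11, boundary inclusive), NEGATIVE below it, MISSING with
#' no scan. When several visits carry a scan the latest one is used.
#'
#' @param visits visit-level data.frame with IID, VISIT, SUVR.
#' @param threshold positivity cutoff (default 1.11).
#' @return data.frame: IID, SUVR (latest, NA if none), status.
#' @export
assign_amyloid <- function(visits, threshold = 1.11) {
  need_cols(visits, c("IID", "VISIT", "SUVR"), "visit table")
  if (any(visits$SUVR < 0, na.rm = TRUE)) stop("negative SUVR value")
  visits <- visits[order(visits$IID, visits$VISIT), , drop = FALSE]
  latest <- vapply(split(visits$SUVR, visits$IID), function(s) {
    s <- s[!is.na(s)]
    if (length(s)) s[length(s)] else NA_real_
  }, numeric(1))
  status <- ifelse(is.na(latest), "MISSING",
                   ifelse(latest >= threshold, "POSITIVE", "NEGATIVE"))
  data.frame(IID = names(latest), SUVR = unname(latest),
             status = unname(status), stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Build the four case/control contrasts
#'
#' 1. AD vs CONTROL; 2. MCI vs CONTROL; 3. amyloid POSITIVE vs NEGATIVE
#' (all labelled subjects, MISSING dropped); 4. among amyloid-positive
#' subjects with baseline MCI: MCI->AD converters vs non-converters.
#' EXCLUDE subjects enter no contrast.
#'
#' @param labels output of [classify_trajectory()].
#' @param amyloid output of [assign_amyloid()].
#' @return named list of data.frames (IID, case) with an `n` attribute
#'   `c(case, control)` on each; errors if any arm is empty.
#' @export
build_contrasts <- function(labels, amyloid) {
  need_cols(labels, c("IID", "label", "baseline_dx", "converter"), "labels")
  need_cols(amyloid, c("IID", "status"), "amyloid")
  m <- merge(labels, amyloid[, c("IID", "status")], by = "IID", all.x = TRUE)
  m$status[is.na(m$status)] <- "MISSING"
  m <- m[m$label != "EXCLUDE", , drop = FALSE]
  mk <- function(ids, case, name) {
    if (!sum(case) || !sum(!case))
      stop("contrast '", name, "' has an empty arm")
    out <- data.frame(IID = ids, case = as.integer(case),
                      stringsAsFactors = FALSE)
    attr(out, "n") <- c(case = sum(case), control = sum(!case))
    out
  }
  ad <- m[m$label %in% c("AD", "CONTROL"), ]
  mci <- m[m$label %in% c("MCI", "CONTROL"), ]
  amy <- m[m$status %in% c("POSITIVE", "NEGATIVE"), ]
  cv <- m[m$baseline_dx == "MCI" & m$status == "POSITIVE" &
            m$label == "MCI", ]
  list(
    ad_vs_control = mk(ad$IID, ad$label == "AD", "ad_vs_control"),
    mci_vs_control = mk(mci$IID, mci$label == "MCI", "mci_vs_control"),
    amyloid_pos_vs_neg = mk(amy$IID, amy$status == "POSITIVE",
                            "amyloid_pos_vs_neg"),
    conversion = mk(cv$IID, cv$converter, "conversion"))
}
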