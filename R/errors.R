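# Classed conditions so callers can distinguish contract violations
# programmatically (tryCatch on the class) instead of matching messages.

abort <- function(message, class) {
  stop(errorCondition(message, class = c(class, "agedetrend_error")))
}

stop_grid_mismatch <- function(msg) abort(msg, "GridMismatch")
stop_parse <- function(msg) abort(msg, "ParseError")
stop_missing_subject <- function(msg) abort(msg, "MissingSubject")
stop_duplicate_subject <- function(msg) abort(msg, "DuplicateSubject")
stop_empty_mask <- function(msg) abort(msg, "EmptyMask")
stop_degenerate_ages <- function(msg) abort(msg, "DegenerateAges")
stop_too_few_subjects <- function(msg) abort(msg, "TooFewSubjects")
stop_rank_deficient <- function(msg) abort(msg, "RankDeficient")
stop_degenerate_split <- function(msg) abort(msg, "DegenerateSplit")
stop_insufficient_misclassifications <- function(msg)
  abort(msg, "InsufficientMisclassifications")
stop_zero_variance <- function(msg) abort(msg, "ZeroVariance")
stop_degenerate_table <- function(msg) abort(msg, "DegenerateTable")
stop_spec_error <- function(msg) abort(msg, "SpecError")

`%||%` <- function(a, b) if (is.null(a)) b else a
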