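`%||%` <- function(a, b) if (is.null(a)) b else a

# Six-record illustrative CVIS dataset (bleeding after PCI) used across
# the unit tests; three cells are missing.
table1_data <- function() {
  data.frame(
    Gender = c("Male", "Female", "Male", NA, "Female", "Male"),
    `PCI History` = c("Yes", "No", "No", "Yes", "Yes", "No"),
    Hemoglobin = c("Abnormal", "Abnormal", NA, "Normal", NA, "Normal"),
    Diabetes = c("No", NA, "No", "No", "No", "No"),
    CRP = c("Abnormal", "Abnormal", "Normal", "Normal", "Abnormal",
            "Normal"),
    Bleeding = c("Yes", "No", "No", "No", "Yes", "No"),
    check.names = FALSE, stringsAsFactors = TRUE)
}

table1_target <- function() pd_target("Bleeding", "Yes")

table1_pattern <- function(r = 2 / 3) {
  pd_pattern(c("PCI History", "Hemoglobin", "CRP"),
             c("Yes", "Abnormal", "Abnormal"), r)
}

# Independent brute-force oracle: record-by-record enumeration with scalar
# loops, no shared code with match_pattern/evaluate_pattern.
oracle_confusion <- function(attrs, values, r, data, target_name, positive) {
  w <- length(attrs)
  TP <- FP <- TN <- FN <- 0L
  for (i in seq_len(nrow(data))) {
    cnt <- 0L
    for (k in seq_len(w)) {
      cell <- as.character(data[[attrs[k]]][i])
      if (!is.na(cell) && cell == values[k]) cnt <- cnt + 1L
    }
    pred <- (cnt / w) >= r
    actual <- as.character(data[[target_name]][i]) == positive
    if (pred && actual) TP <- TP + 1L
    else if (pred && !actual) FP <- FP + 1L
    else if (!pred && !actual) TN <- TN + 1L
    else FN <- FN + 1L
  }
  list(TP = TP, FP = FP, TN = TN, FN = FN)
}

# Exhaustive sweep of the threshold grid by the oracle above; ties to the
# largest r, mirroring the documented default.
oracle_grid_best <- function(attrs, values, data, target_name, positive) {
  w <- length(attrs)
  best_g <- -1
  best_k <- NA_integer_
  for (k in seq_len(w)) {
    cc <- oracle_confusion(attrs, values, k / w, data, target_name, positive)
    sen <- if (cc$TP + cc$FN > 0) cc$TP / (cc$TP + cc$FN) else 0
    spec <- if (cc$TN + cc$FP > 0) cc$TN / (cc$TN + cc$FP) else 0
    g <- sqrt(sen * spec)
    if (g >= best_g) {  # >= keeps the largest tying k
      best_g <- g
      best_k <- k
    }
  }
  list(k = best_k, r = best_k / w, g_mean = best_g)
}
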