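# Published coefficient sets for the four comparator steatosis indices,
# transcribed from their original publications and kept in one place so
# they can be audited. Units: TG mg/dL, GGT/AST/ALT IU/L, BMI kg/m2,
# waist cm, insulin uIU/mL, age years.
index_coefficients <- function() {
  list(
    fli = c(log_tg = 0.953, bmi = 0.139, log_ggt = 0.718, waist = 0.053,
            intercept = -15.745),
    nafld_lfs = c(intercept = -2.89, mets = 1.18, t2dm = 0.45,
                  insulin = 0.15, ast = 0.04, ast_alt = -0.94),
    hsi = c(alt_ast = 8, bmi = 1, dm = 2, female = 2),
    fsi = c(intercept = -7.981, age = 0.011, female = -0.146, bmi = 0.173,
            tg = 0.007, htn = 0.593, dm = 0.789, alt_ast_ge_1.33 = 1.1)
  )
}

#' Fatty liver index (FLI)
#'
#' Logistic transform of
#' `0.953 ln(TG) + 0.139 BMI + 0.718 ln(GGT) + 0.053 waist - 15.745`,
#' scaled to 0-100.
#'
#' @param TG Triglycerides, mg/dL (> 0).
#' @param BMI Body mass index, kg/m2.
#' @param GGT Gamma-glutamyl transferase, IU/L (> 0).
#' @param waist Waist circumference, cm.
#' @return FLI in [0, 100] (vectorized).
#' @export
fli <- function(TG, BMI, GGT, waist) {
  if (any(TG <= 0) || any(GGT <= 0)) stop("TG and GGT must be positive")
  co <- index_coefficients()$fli
  L <- co["log_tg"] * log(TG) + co["bmi"] * BMI +
    co["log_ggt"] * log(GGT) + co["waist"] * waist + co["intercept"]
  unname(stats::plogis(L) * 100)
}

#' NAFLD liver fat score (NAFLD-LFS)
#'
#' `-2.89 + 1.18 MetS + 0.45 T2DM + 0.15 insulin + 0.04 AST
#'  - 0.94 (AST/ALT)`.
#'
#' @param mets Metabolic-syndrome flag (0/1 or logical).
#' @param t2dm Type-2-diabetes flag.
#' @param insulin Fasting insulin, uIU/mL.
#' @param AST,ALT Transaminases, IU/L (ALT > 0).
#' @return Score (vectorized; unbounded).
#' @export
nafld_lfs <- function(mets, t2dm, insulin, AST, ALT) {
  if (any(ALT <= 0)) stop("ALT must be positive")
  co <- index_coefficients()$nafld_lfs
  unname(co["intercept"] + co["mets"] * as.numeric(mets) +
           co["t2dm"] * as.numeric(t2dm) + co["insulin"] * insulin +
           co["ast"] * AST + co["ast_alt"] * (AST / ALT))
}

#' Hepatic steatosis index (HSI)
#'
#' `8 (ALT/AST) + BMI + 2 DM + 2 female`.
#'
#' @param ALT,AST Transaminases, IU/L (AST > 0).
#' @param BMI Body mass index, kg/m2.
#' @param dm Diabetes flag.
#' @param female Female-sex flag.
#' @return Score (vectorized).
#' @export
hsi <- function(ALT, AST, BMI, dm, female) {
  if (any(AST <= 0)) stop("AST must be positive")
  co <- index_coefficients()$hsi
  unname(co["alt_ast"] * (ALT / AST) + co["bmi"] * BMI +
           co["dm"] * as.numeric(dm) + co["female"] * as.numeric(female))
}

#' Framingham steatosis index (FSI)
#'
#' Logistic model
#' `-7.981 + 0.011 age - 0.146 female + 0.173 BMI + 0.007 TG + 0.593 HTN
#'  + 0.789 DM + 1.1 I(ALT/AST >= 1.33)`, reported on the probability
#' scale.
#'
#' @param age Years.
#' @param female Female-sex flag.
#' @param BMI Body mass index, kg/m2.
#' @param TG Triglycerides, mg/dL.
#' @param AST,ALT Transaminases, IU/L (AST > 0).
#' @param dm Diabetes flag; `htn` hypertension flag.
#' @param htn Hypertension flag.
#' @return Probability in [0, 1] (vectorized).
#' @export
fsi <- function(age, female, BMI, TG, AST, ALT, dm, htn) {
  if (any(AST <= 0)) stop("AST must be positive")
  co <- index_coefficients()$fsi
  lp <- co["intercept"] + co["age"] * age + co["female"] * as.numeric(female) +
    co["bmi"] * BMI + co["tg"] * TG + co["htn"] * as.numeric(htn) +
    co["dm"] * as.numeric(dm) + co["alt_ast_ge_1.33"] * as.numeric(ALT / AST >= 1.33)
  unname(stats::plogis(lp))
}

#' Default binarization thresholds for the indices
#'
#' Each index's published rule-in cutoff where one exists: FLI >= 60,
#' HSI >= 36, NAFLD-LFS >= -0.640, FSI >= 0.5.
#' @return Named numeric vector.
#' @export
index_thresholds <- function() {
  c(fli = 60, nafld_lfs = -0.640, hsi = 36, fsi = 0.5)
}

#' Compute all four steatosis indices for a clinical table
#'
#' @param clinical Data frame with columns `sex`, `age`, `BMI`, `waist`,
#'   `TG`, `GGT`, `AST`, `ALT`, `insulin`, `diabetes`, `hypertension`,
#'   `mets`.
#' @param thresholds Named cutoffs for the binary calls (default
#'   [index_thresholds()]).
#' @return Data frame with a score and a binary call per index, plus the
#'   thresholds as an attribute.
#' @export
steatosis_indices <- function(clinical, thresholds = index_thresholds()) {
  req <- c("sex", "age", "BMI", "waist", "TG", "GGT", "AST", "ALT",
           "insulin", "diabetes", "hypertension", "mets")
  miss <- setdiff(req, names(clinical))
  if (length(miss) > 0) stop("missing covariate: ", paste(miss, collapse = ", "))
  female <- clinical$sex == "F"
  out <- data.frame(
    fli = fli(clinical$TG, clinical$BMI, clinical$GGT, clinical$waist),
    nafld_lfs = nafld_lfs(clinical$mets, clinical$diabetes, clinical$insulin,
                          clinical$AST, clinical$ALT),
    hsi = hsi(clinical$ALT, clinical$AST, clinical$BMI, clinical$diabetes,
              female),
    fsi = fsi(clinical$age, female, clinical$BMI, clinical$TG,
              clinical$AST, clinical$ALT, clinical$diabetes,
              clinical$hypertension)
  )
  for (nm in names(thresholds))
    out[[paste0(nm, "_call")]] <- out[[nm]] >= thresholds[nm]
  attr(out, "thresholds") <- thresholds
  out
}

#' Compare predictors on one shared test partition
#'
#' One row per predictor (clinical index or classifier score) with AUROC,
#' accuracy, kappa and F1, all computed on the same samples against the
#' same truth; mismatched lengths are refused.
#'
#' @param predictors Named list of numeric score vectors.
#' @param truth Two-class label vector (positive = fatty liver).
#' @param thresholds Named binarization cutoff per predictor (default 0.5).
#' @return Data frame with `predictor`, `threshold`, `auroc`, `accuracy`,
#'   `kappa`, `f1`.
#' @export
compare_predictors <- function(predictors, truth, thresholds = NULL) {
  stopifnot(is.list(predictors), length(predictors) >= 1)
  n <- length(truth)
  rows <- lapply(names(predictors), function(nm) {
    sc <- predictors[[nm]]
    if (length(sc) != n)
      stop("predictor '", nm, "' scored on a different sample set")
    thr <- if (!is.null(thresholds) && nm %in% names(thresholds))
      thresholds[[nm]] else 0.5
    ev <- evaluate_scores(sc, truth, threshold = thr, ci = FALSE)
    data.frame(predictor = nm, threshold = thr, auroc = ev$auroc,
               accuracy = ev$accuracy, kappa = ev$kappa, f1 = ev$f1,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
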