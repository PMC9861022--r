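# Seeded synthetic-cohort generation through a per-sex Gaussian copula, plus
# the cohort CSV reader/writer.

.cohort_columns <- c("subject_id", "sex", "age", "height_cm", "weight_kg",
                     "waist_cm", "sbp_mmhg", "dbp_mmhg", "total_chol_mgdl",
                     "hdl_mgdl", "ldl_mgdl", "tg_mgdl", "glucose_mgdl",
                     "smoker", "social_class")

# Map copula variable names to CSV column names.
.var_to_col <- c(height = "height_cm", weight = "weight_kg", waist = "waist_cm",
                 sbp = "sbp_mmhg", dbp = "dbp_mmhg", total_chol = "total_chol_mgdl",
                 hdl = "hdl_mgdl", tg = "tg_mgdl", glucose = "glucose_mgdl")

# Log-normal parameters matching a target mean and SD on the raw scale.
.lnorm_pars <- function(mean, sd) {
  sigma2 <- log(1 + (sd / mean)^2)
  list(meanlog = log(mean) - sigma2 / 2, sdlog = sqrt(sigma2))
}

# Draw one block of latent-Gaussian rows mapped through the marginals.
.draw_block <- function(n, marg, L) {
  k <- nrow(marg)
  z <- matrix(stats::rnorm(n * k), nrow = n) %*% t(L)
  out <- matrix(NA_real_, n, k, dimnames = list(NULL, rownames(marg)))
  for (j in seq_len(k)) {
    if (marg$family[j] == "lognormal") {
      p <- .lnorm_pars(marg$mean[j], marg$sd[j])
      out[, j] <- exp(p$meanlog + p$sdlog * z[, j])
    } else {
      out[, j] <- marg$mean[j] + marg$sd[j] * z[, j]
    }
  }
  out
}

# Generate n continuous rows for one sex, rejecting draws outside the
# truncation bounds or with sbp <= dbp and redrawing them.
.generate_sex_block <- function(n, sexspec, max_rounds = 200) {
  marg <- sexspec$marginals
  R <- sexspec$correlation[rownames(marg), rownames(marg)]
  # PSD (possibly semi-definite) square root via eigendecomposition
  e <- eigen(R, symmetric = TRUE)
  L <- e$vectors %*% diag(sqrt(pmax(e$values, 0)), nrow(R))
  out <- .draw_block(n, marg, L)
  bad <- which(.violates_bounds(out, marg))
  rounds <- 0
  while (length(bad) > 0) {
    rounds <- rounds + 1
    if (rounds > max_rounds)
      stop("rejection sampling failed to satisfy truncation bounds; check spec")
    out[bad, ] <- .draw_block(length(bad), marg, L)
    bad <- bad[.violates_bounds(out[bad, , drop = FALSE], marg)]
  }
  out
}

.violates_bounds <- function(x, marg) {
  viol <- rep(FALSE, nrow(x))
  for (j in seq_len(nrow(marg))) {
    v <- rownames(marg)[j]
    viol <- viol | x[, v] < marg$lower[j] | x[, v] > marg$upper[j]
  }
  viol | x[, "sbp"] <= x[, "dbp"]
}

#' Generate a synthetic cohort
#'
#' Draws `n` subject records from the per-sex Gaussian copula defined by a
#' cohort specification. Sex is Bernoulli with the spec's male fraction; each
#' sex's continuous variables come from a latent multivariate Gaussian with
#' the cohort specification's correlation matrix, mapped through Gaussian
#' marginals (heights,
#' weights, waist, blood pressure, cholesterol, HDL) or moment-matched
#' log-normal marginals (triglycerides, glucose). Rows falling outside the
#' physiological truncation bounds, or with systolic not exceeding diastolic
#' pressure, are rejected and redrawn. Age is drawn uniformly within a
#' sampled age band; LDL is derived with the Friedewald formula and is
#' missing when triglycerides reach 400 mg/dL.
#'
#' The same `(spec, n, seed)` always yields the identical cohort.
#'
#' @param spec A `cohort_spec` object, e.g. [default_spec()].
#' @param n Number of subjects (positive integer).
#' @param seed Integer random seed.
#' @return A data.frame with one row per subject and columns
#'   `subject_id, sex, age, height_cm, weight_kg, waist_cm, sbp_mmhg,
#'   dbp_mmhg, total_chol_mgdl, hdl_mgdl, ldl_mgdl, tg_mgdl, glucose_mgdl,
#'   smoker, social_class`.
#' @examples
#' cohort <- generate_cohort(default_spec(), n = 100, seed = 1)
#' summary(cohort$waist_cm)
#' @export
generate_cohort <- function(spec, n, seed) {
  validate_spec(spec)
  if (!is.numeric(n) || length(n) != 1 || n < 1 || n != round(n))
    stop("`n` must be a positive integer")
  if (!is.numeric(seed) || length(seed) != 1)
    stop("`seed` must be a single integer")
  n <- as.integer(n)

  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))

  sex <- ifelse(stats::runif(n) < spec$male_fraction, "M", "F")
  cont <- matrix(NA_real_, n, length(.copula_vars),
                 dimnames = list(NULL, .copula_vars))
  age <- integer(n)
  smoker <- integer(n)
  social <- character(n)

  for (s in c("F", "M")) {
    idx <- which(sex == s)
    if (!length(idx)) next
    sexspec <- if (s == "M") spec$male else spec$female
    cont[idx, ] <- .generate_sex_block(length(idx), sexspec)

    band <- sample(nrow(sexspec$age_bands), length(idx), replace = TRUE,
                   prob = sexspec$age_probs)
    lo <- sexspec$age_bands[band, "from"]
    hi <- sexspec$age_bands[band, "to"]
    age[idx] <- as.integer(lo + floor(stats::runif(length(idx)) * (hi - lo + 1)))
    smoker[idx] <- as.integer(stats::runif(length(idx)) < sexspec$smoker_prob)
    social[idx] <- sample(names(sexspec$social_class_probs), length(idx),
                          replace = TRUE, prob = sexspec$social_class_probs)
  }

  cohort <- data.frame(
    subject_id = sprintf("S%07d", seq_len(n)),
    sex = sex,
    age = age,
    stringsAsFactors = FALSE
  )
  for (v in .copula_vars) cohort[[.var_to_col[[v]]]] <- cont[, v]
  cohort$ldl_mgdl <- friedewald_ldl(cohort$total_chol_mgdl, cohort$hdl_mgdl,
                                    cohort$tg_mgdl)
  cohort$smoker <- smoker
  cohort$social_class <- social
  cohort[, .cohort_columns]
}

#' Write a cohort to CSV
#'
#' Writes the documented cohort schema: UTF-8, comma-separated, dot decimal
#' separator, missing values as empty cells, continuous measurements with 10
#' decimal places so a write/read round trip preserves values to better than
#' 1e-9. Output bytes are fully determined by the cohort contents.
#'
#' @param cohort Cohort data.frame as returned by [generate_cohort()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  missing_cols <- setdiff(.cohort_columns, names(cohort))
  if (length(missing_cols))
    stop("cohort lacks required columns: ", paste(missing_cols, collapse = ", "))
  out <- cohort[, .cohort_columns]
  num <- vapply(out, is.numeric, logical(1)) &
    !(names(out) %in% c("age", "smoker"))
  for (j in which(num)) {
    x <- sprintf("%.10f", out[[j]])
    x[is.na(out[[j]])] <- ""
    out[[j]] <- x
  }
  cols <- lapply(out, function(x) {
    x <- as.character(x)
    x[is.na(x)] <- ""
    x
  })
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(.cohort_columns, collapse = ","), con)
  writeLines(do.call(paste, c(cols, sep = ",")), con)
  invisible(path)
}

#' Read a cohort from CSV
#'
#' Parses the documented cohort schema and validates each row: sex must be
#' `F`/`M`, smoker `0`/`1`, social class `I`/`II`/`III`, and every
#' measurement numeric. Empty cells become missing values. Malformed rows are
#' rejected with the offending row number.
#'
#' @param path Path to a cohort CSV written by [write_cohort()].
#' @return A cohort data.frame.
#' @export
read_cohort <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character", na.strings = "")
  missing_cols <- setdiff(.cohort_columns, names(raw))
  if (length(missing_cols))
    stop("cohort file lacks required columns: ",
         paste(missing_cols, collapse = ", "))

  fail <- function(rows, what) {
    stop(sprintf("parse error at row %d: %s", rows[1] + 1L, what))
  }
  bad <- which(!raw$sex %in% c("F", "M"))
  if (length(bad)) fail(bad, sprintf("unknown sex code '%s'", raw$sex[bad[1]]))
  bad <- which(!raw$smoker %in% c("0", "1"))
  if (length(bad)) fail(bad, sprintf("invalid smoker code '%s'", raw$smoker[bad[1]]))
  bad <- which(!raw$social_class %in% c("I", "II", "III"))
  if (length(bad)) fail(bad, sprintf("unknown social class code '%s'",
                                     raw$social_class[bad[1]]))

  numeric_cols <- c("age", unname(.var_to_col), "ldl_mgdl")
  out <- raw
  for (col in numeric_cols) {
    v <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(v) & !is.na(raw[[col]]))
    if (length(bad)) fail(bad, sprintf("non-numeric value '%s' in column %s",
                                       raw[[col]][bad[1]], col))
    # only ldl may be missing
    if (col != "ldl_mgdl") {
      bad <- which(is.na(v))
      if (length(bad)) fail(bad, sprintf("missing value in column %s", col))
    }
    out[[col]] <- v
  }
  out$age <- as.integer(out$age)
  out$smoker <- as.integer(out$smoker)
  out[, .cohort_columns]
}
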