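#' Default demographic category frequencies
#'
#' Marginal frequencies for sex, race (five anonymized groups) and insurance
#' used by the cohort generator; roughly a 52/48 male/female split, a
#' five-group race distribution and a public/private/other insurance split
#' typical of a large pediatric health-system cohort. Purely marginal: no
#' claim of joint demographic realism.
#'
#' @return named list of named probability vectors.
#' @export
defaultCategoryFreqs <- function() {
  list(
    sex = c(male = 0.519, female = 0.481),
    race = c(A = 0.042, B = 0.302, C = 0.429, D = 0.089, E = 0.138),
    insurance = c(public = 0.535, private = 0.462, other = 0.003)
  )
}

#' Construct a cohort simulation configuration
#'
#' See [CohortConfig] for the meaning of each parameter. Defaults give a
#' mid-sized cohort born 2014-2022 with a mid-2023 extraction date, so
#' follow-up length is a deterministic function of birth date (administrative
#' right-censoring).
#'
#' @param nPatients number of children.
#' @param birthYearRange integer `c(min, max)` birth years.
#' @param extractionYear decimal year of data extraction.
#' @param dropoutRate per-year exponential dropout hazard.
#' @param baselineHazards per-yearly-bin discrete event hazards in `[0,1)`.
#' @param covariateEffects named log-hazard-ratios keyed `"attribute:level"`.
#' @param prevalenceTrend additive log-hazard drift per birth year.
#' @param referenceYear centring year for the trend.
#' @param vocabularySize,meanCodesPerYear code-process parameters.
#' @param riskCodeFraction,riskEnrichment,riskEffect risk-code parameters.
#' @param eraCodeFraction,eraDrift era-code (secular drift) parameters.
#' @param hazardLink `"logit"` or `"cloglog"`.
#' @param immuneFraction explicit never-event fraction (default 0).
#' @param categoryFreqs demographic marginals, see [defaultCategoryFreqs()].
#' @param seed integer simulation seed.
#' @return a validated [CohortConfig].
#' @export
cohortConfig <- function(nPatients,
                         birthYearRange = c(2014L, 2022L),
                         extractionYear = 2023.42,
                         dropoutRate = 0,
                         baselineHazards = rep(0.02, 8),
                         covariateEffects = c("sex:male" = 0.5),
                         prevalenceTrend = 0,
                         referenceYear = mean(birthYearRange),
                         vocabularySize = 120L,
                         meanCodesPerYear = 8,
                         riskCodeFraction = 0.2,
                         eraCodeFraction = 0.2,
                         riskEnrichment = 1,
                         eraDrift = 0.4,
                         riskEffect = 0.8,
                         hazardLink = c("logit", "cloglog"),
                         immuneFraction = 0,
                         categoryFreqs = defaultCategoryFreqs(),
                         seed = 1L) {
  hazardLink <- match.arg(hazardLink)
  if (is.null(covariateEffects)) covariateEffects <- numeric()
  covariateEffects <- unlist(covariateEffects)
  if (length(covariateEffects) && is.null(names(covariateEffects)))
    stop("covariateEffects must be named 'attribute:level'", call. = FALSE)
  new("CohortConfig",
      nPatients = as.integer(nPatients),
      birthYearRange = as.integer(birthYearRange),
      extractionYear = as.numeric(extractionYear),
      dropoutRate = as.numeric(dropoutRate),
      baselineHazards = as.numeric(baselineHazards),
      covariateEffects = structure(as.numeric(covariateEffects),
                                   names = names(covariateEffects)),
      prevalenceTrend = as.numeric(prevalenceTrend),
      referenceYear = as.numeric(referenceYear),
      vocabularySize = as.integer(vocabularySize),
      meanCodesPerYear = as.numeric(meanCodesPerYear),
      riskCodeFraction = as.numeric(riskCodeFraction),
      eraCodeFraction = as.numeric(eraCodeFraction),
      riskEnrichment = as.numeric(riskEnrichment),
      eraDrift = as.numeric(eraDrift),
      riskEffect = as.numeric(riskEffect),
      hazardLink = hazardLink,
      immuneFraction = as.numeric(immuneFraction),
      categoryFreqs = lapply(categoryFreqs, function(x) x / sum(x)),
      seed = as.integer(seed))
}

#' Read a cohort configuration from a YAML file
#'
#' The file may contain any subset of the [cohortConfig()] arguments (nested
#' maps for `covariateEffects` and `categoryFreqs`); unknown keys are an
#' error, and the result is validated on construction.
#'
#' @param path path to a YAML file.
#' @return a [CohortConfig].
#' @export
readCohortConfig <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(cohortConfig))
  bad <- setdiff(names(raw), known)
  if (length(bad))
    stop("unknown configuration keys: ", paste(bad, collapse = ", "),
         call. = FALSE)
  if (!is.null(raw$covariateEffects))
    raw$covariateEffects <- unlist(raw$covariateEffects)
  if (!is.null(raw$categoryFreqs))
    raw$categoryFreqs <- lapply(raw$categoryFreqs, unlist)
  do.call(cohortConfig, raw)
}

.linkHazard <- function(h0, eta, link) {
  # h0: per-bin baseline hazards (length K); eta: per-patient linear predictor
  K <- length(h0)
  n <- length(eta)
  if (link == "logit") {
    H <- stats::plogis(outer(eta, stats::qlogis(h0), `+`))
  } else { # cloglog: exactly proportional piecewise-exponential hazards
    H <- 1 - outer(exp(eta), 1 - h0, function(e, s) s^e)
  }
  H[, h0 == 0] <- 0
  H
}

.covariateEta <- function(p, effects) {
  eta <- numeric(nrow(p))
  for (nm in names(effects)) {
    parts <- strsplit(nm, ":", fixed = TRUE)[[1]]
    if (length(parts) != 2L || !parts[1] %in% c("sex", "race", "insurance"))
      stop("covariateEffects names must be 'sex:level', 'race:level' or ",
           "'insurance:level'; got '", nm, "'", call. = FALSE)
    eta <- eta + effects[[nm]] * (p[[parts[1]]] == parts[2])
  }
  eta
}

#' Generate a synthetic cohort
#'
#' Simulates children under the configured discrete-time hazard model. Event
#' times arise from yearly-bin hazards
#' `h_i(k) = link(baseline_k, covariate effects + trend + risk propensity)`
#' with uniform within-bin jitter; a child with no bin firing inside the
#' horizon never experiences the event (`event_time = Inf`). Censoring is the
#' minimum of the administrative censoring age (extraction date minus birth
#' date) and an optional exponential dropout time. Code sequences are a
#' marked Poisson process at `meanCodesPerYear` truncated at the observed
#' time, with risk codes enriched in high-hazard children and era codes
#' drifting with birth year. Deterministic given `config@seed`.
#'
#' @param config a [CohortConfig].
#' @return a [PatientCohort].
#' @export
generateCohort <- function(config) {
  validObject(config)
  if (config@extractionYear <= config@birthYearRange[2])
    stop("extractionYear must exceed the latest birth year", call. = FALSE)
  withSeed(config@seed, {
    n <- config@nPatients
    h0 <- config@baselineHazards
    K <- length(h0)
    by <- sample(seq(config@birthYearRange[1], config@birthYearRange[2]),
                 n, replace = TRUE)
    offset <- stats::runif(n)
    cAdmin <- pmax(config@extractionYear - (by + offset), 1e-6)
    cDrop <- if (config@dropoutRate > 0)
      stats::rexp(n, rate = config@dropoutRate) else rep(Inf, n)
    C <- pmin(cAdmin, cDrop)

    freqs <- config@categoryFreqs
    p <- data.frame(
      patient_id = sprintf("p%06d", seq_len(n)),
      birth_year = as.integer(by),
      sex = sample(names(freqs$sex), n, TRUE, prob = freqs$sex),
      race = sample(names(freqs$race), n, TRUE, prob = freqs$race),
      insurance = sample(names(freqs$insurance), n, TRUE,
                         prob = freqs$insurance),
      stringsAsFactors = FALSE)

    u <- stats::rnorm(n) # latent risk propensity, shared by hazard and codes
    eta <- .covariateEta(p, config@covariateEffects) +
      config@prevalenceTrend * (by - config@referenceYear) +
      config@riskEffect * u
    H <- .linkHazard(h0, eta, config@hazardLink)
    fired <- matrix(stats::runif(n * K), n, K) < H
    firstBin <- apply(fired, 1L, function(r) {
      w <- which(r); if (length(w)) w[1] else NA_integer_
    })
    jitter <- stats::runif(n)
    E <- ifelse(is.na(firstBin), Inf, (firstBin - 1) + jitter)
    if (config@immuneFraction > 0) {
      immune <- stats::runif(n) < config@immuneFraction
      E[immune] <- Inf
    }

    p$event_time <- E
    p$censoring_time <- C
    p$time <- pmin(E, C)
    p$event <- as.integer(E <= C)

    codes <- .generateCodes(p, u, config)
    new("PatientCohort", patients = p, codes = codes,
        metadata = list(config = config, seed = config@seed))
  })
}

.tokenLabels <- function(vocabularySize) sprintf("c%04d", seq_len(vocabularySize))

# marked point process of codes. Marks are drawn in two stages so the two
# signals stay orthogonal: risk vs non-risk by the latent risk propensity,
# then era vs background within the non-risk codes by birth era (coding
# drift changes WHICH routine codes appear, it does not dilute the clinical
# risk signal).
.generateCodes <- function(p, u, config) {
  n <- nrow(p)
  V <- config@vocabularySize
  nRisk <- round(V * config@riskCodeFraction)
  nEra <- round(V * config@eraCodeFraction)
  nBg <- V - nRisk - nEra
  counts <- stats::rpois(n, config@meanCodesPerYear * p$time)
  idx <- rep.int(seq_len(n), counts)
  if (length(idx) == 0L)
    return(data.frame(patient_id = character(), age = numeric(),
                      code = character(), stringsAsFactors = FALSE))
  ages <- stats::runif(length(idx)) * p$time[idx]
  keep <- ages < p$time[idx]
  idx <- idx[keep]; ages <- ages[keep]

  fR <- config@riskCodeFraction
  pRisk <- if (nRisk > 0) {
    w <- fR * exp(config@riskEnrichment * u)
    w / (w + (1 - fR))
  } else numeric(n)
  fE <- if (nRisk < V) config@eraCodeFraction / (1 - fR) else 0
  pEra <- if (nEra > 0) {
    w <- fE * exp(config@eraDrift * (p$birth_year - config@referenceYear))
    w / (w + (1 - fE))
  } else numeric(n)

  v <- stats::runif(length(idx))
  v2 <- stats::runif(length(idx))
  isRisk <- v < pRisk[idx]
  isEra <- !isRisk & v2 < pEra[idx]
  cat <- ifelse(isRisk, 1L, ifelse(isEra, 2L, 3L))
  tok <- integer(length(idx))
  isR <- cat == 1L; isE <- cat == 2L; isB <- cat == 3L
  if (any(isR)) tok[isR] <- ceiling(stats::runif(sum(isR)) * nRisk)
  if (any(isE)) tok[isE] <- nRisk + ceiling(stats::runif(sum(isE)) * nEra)
  if (any(isB)) tok[isB] <- nRisk + nEra + ceiling(stats::runif(sum(isB)) * nBg)
  tok <- pmax(tok, 1L)

  labels <- .tokenLabels(V)
  codes <- data.frame(patient_id = p$patient_id[idx], age = ages,
                      code = labels[tok], stringsAsFactors = FALSE)
  codes <- codes[order(match(codes$patient_id, p$patient_id), codes$age), ]
  rownames(codes) <- NULL
  codes
}

#' @describeIn PatientCohort number of patients.
#' @param object,x a `PatientCohort`.
#' @export
setGeneric("nPatients", function(x) standardGeneric("nPatients"))

#' @rdname PatientCohort
#' @export
setMethod("nPatients", "PatientCohort", function(x) nrow(x@patients))

#' @rdname PatientCohort
#' @export
setGeneric("patients", function(x) standardGeneric("patients"))

#' @rdname PatientCohort
#' @export
setMethod("patients", "PatientCohort", function(x) x@patients)

#' @rdname PatientCohort
#' @export
setGeneric("codeEvents", function(x) standardGeneric("codeEvents"))

#' @rdname PatientCohort
#' @export
setMethod("codeEvents", "PatientCohort", function(x) x@codes)

setMethod("show", "PatientCohort", function(object) {
  p <- object@patients
  cat("PatientCohort with", nrow(p), "patients,",
      nrow(object@codes), "code events\n")
  if (nrow(p)) {
    cat(sprintf("  events: %d (%.1f%%), median follow-up %.2f y\n",
                sum(p$event), 100 * mean(p$event),
                stats::median(p$time)))
    cat(sprintf("  birth years %d-%d\n", min(p$birth_year), max(p$birth_year)))
  }
  invisible(object)
})

#' Subset a cohort by patient id
#'
#' @param cohort a [PatientCohort].
#' @param ids patient identifiers to keep (order preserved).
#' @return a new [PatientCohort]; the input is not modified.
#' @export
subsetCohort <- function(cohort, ids) {
  p <- cohort@patients[cohort@patients$patient_id %in% ids, , drop = FALSE]
  cds <- cohort@codes[cohort@codes$patient_id %in% ids, , drop = FALSE]
  rownames(p) <- NULL; rownames(cds) <- NULL
  new("PatientCohort", patients = p, codes = cds, metadata = cohort@metadata)
}

#' Write / read a cohort as flat CSV files
#'
#' `writeCohort()` writes `patients.csv` (one row per patient; `event_time`
#' uses `Inf` for never-event children) and `codes.csv` (long format
#' `patient_id, age, code`) into `dir`. `readCohort()` reads them back.
#'
#' @param cohort a [PatientCohort].
#' @param dir directory to write to / read from (created if needed).
#' @return `writeCohort()` returns `dir` invisibly; `readCohort()` a
#'   [PatientCohort].
#' @export
writeCohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(cohort@patients, file.path(dir, "patients.csv"),
                   row.names = FALSE)
  utils::write.csv(cohort@codes, file.path(dir, "codes.csv"),
                   row.names = FALSE)
  invisible(dir)
}

#' @rdname writeCohort
#' @export
readCohort <- function(dir) {
  p <- utils::read.csv(file.path(dir, "patients.csv"),
                       colClasses = c(patient_id = "character",
                                      birth_year = "integer",
                                      sex = "character", race = "character",
                                      insurance = "character",
                                      event_time = "numeric",
                                      censoring_time = "numeric",
                                      time = "numeric", event = "integer"))
  cds <- utils::read.csv(file.path(dir, "codes.csv"),
                         colClasses = c(patient_id = "character",
                                        age = "numeric", code = "character"))
  new("PatientCohort", patients = p, codes = cds, metadata = list())
}
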