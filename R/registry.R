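## Feature registry: the 84-row default schema, YAML (de)serialization and
## code lookup.  ICD-9 diagnosis codes are matched by the integer part before
## the first dot against chapter/subchapter ranges; CPT procedures by 5-digit
## numeric ranges; HCPCS level II by its letter prefix; labs, vitals and
## symptom groups by name.

.mk_feature <- function(row, name, group, kind, codes, meta = list()) {
  list(row = as.integer(row), name = name, group = group, kind = kind,
       codes = codes, meta = meta)
}

.registry_from_list <- function(feats, version = "custom") {
  feats <- feats[order(vapply(feats, `[[`, integer(1), "row"))]
  ft <- S4Vectors::DataFrame(
    row   = vapply(feats, `[[`, integer(1), "row"),
    name  = vapply(feats, `[[`, character(1), "name"),
    group = vapply(feats, `[[`, character(1), "group"),
    kind  = vapply(feats, `[[`, character(1), "kind"))
  ft$codes <- lapply(feats, `[[`, "codes")
  ft$meta  <- lapply(feats, function(f) if (is.null(f$meta)) list() else f$meta)
  new("FeatureRegistry", features = ft, version = version)
}

## The 21 three-digit mental-disorder diagnosis groups (ICD-9 290-319, one
## extra level of detail; 310-319 collapsed into a single residual group).
.mental_groups <- function() {
  nm <- c("dementias", "alcohol-induced mental disorders",
          "drug-induced mental disorders",
          "transient organic psychotic conditions",
          "other organic psychotic conditions", "schizophrenic disorders",
          "episodic mood disorders", "delusional disorders",
          "other nonorganic psychoses", "pervasive developmental disorders",
          "anxiety, dissociative and somatoform disorders",
          "personality disorders", "sexual and gender identity disorders",
          "alcohol dependence syndrome", "drug dependence",
          "nondependent abuse of drugs",
          "physiological malfunction arising from mental factors",
          "special symptoms or syndromes", "acute reaction to stress",
          "adjustment reaction")
  out <- mapply(function(i, n) .mk_feature(i + 1L, n, "diagnosis_mental",
                                           "binary", sprintf("%03d", 289 + i)),
                seq_along(nm), nm, SIMPLIFY = FALSE)
  c(out, list(.mk_feature(22L, "other mental disorders", "diagnosis_mental",
                          "binary", "310-319")))
}

## Non-mental ICD-9 chapter groups in ascending code order; this ordering
## places diseases of the digestive system (520-579) on row 30.  Congenital
## anomalies and perinatal conditions share a row, as do the V/E supplementary
## classifications.
.other_dx_groups <- function() {
  spec <- list(
    c("infectious and parasitic diseases", "001-139"),
    c("neoplasms", "140-239"),
    c("endocrine, nutritional, metabolic and immunity disorders", "240-279"),
    c("diseases of blood and blood-forming organs", "280-289"),
    c("diseases of the nervous system and sense organs", "320-389"),
    c("diseases of the circulatory system", "390-459"),
    c("diseases of the respiratory system", "460-519"),
    c("diseases of the digestive system", "520-579"),
    c("diseases of the genitourinary system", "580-629"),
    c("complications of pregnancy, childbirth and the puerperium", "630-679"),
    c("diseases of the skin and subcutaneous tissue", "680-709"),
    c("diseases of the musculoskeletal system and connective tissue",
      "710-739"),
    c("congenital anomalies and perinatal conditions", "740-779"),
    c("symptoms, signs and ill-defined conditions", "780-799"),
    c("injury and poisoning", "800-999"))
  out <- mapply(function(i, s) .mk_feature(22L + i, s[1], "diagnosis_other",
                                           "binary", s[2]),
                seq_along(spec), spec, SIMPLIFY = FALSE)
  c(out, list(.mk_feature(38L, "supplementary classification (V and E codes)",
                          "diagnosis_other", "binary",
                          c("V01-V91", "E000-E999"))))
}

## Seven CPT procedure groups by conventional numeric ranges (configurable via
## custom registries); HCPCS level II is matched by its letter prefix.
.procedure_groups <- function() {
  spec <- list(
    list("anesthesia", "cpt:00100-01999"),
    list("surgery", "cpt:10004-69990"),
    list("radiology", "cpt:70010-79999"),
    list("pathology and laboratory", "cpt:80047-89398"),
    list("medicine", c("cpt:90281-99199", "cpt:99500-99607")),
    list("evaluation and management", "cpt:99202-99499"),
    list("HCPCS level II", "hcpcs:A-V"))
  mapply(function(i, s) .mk_feature(38L + i, s[[1]], "procedure_group",
                                    "binary", s[[2]]),
         seq_along(spec), spec, SIMPLIFY = FALSE)
}

## Ten most frequent labs with default population mean/sd used to score
## abnormality when no cohort-fitted standardizer is supplied (conventional
## adult reference magnitudes; the pipeline refits from the cohort).
.lab_groups <- function() {
  labs <- list(
    list("glucose", 100, 25), list("hemoglobin", 14, 1.8),
    list("erythrocytes", 4.8, 0.6), list("creatinine", 1.0, 0.35),
    list("leukocytes", 7.5, 2.5), list("carbon dioxide", 25, 3),
    list("potassium", 4.2, 0.45), list("sodium", 140, 3),
    list("chloride", 102, 4), list("urea nitrogen", 15, 6))
  mapply(function(i, l) {
    .mk_feature(45L + i, l[[1]], "lab", "graded",
                paste0("lab:", gsub(" ", "_", l[[1]])),
                meta = list(mean = l[[2]], sd = l[[3]], cap = 3))
  }, seq_along(labs), labs, SIMPLIFY = FALSE)
}

## Five vitals with normal range [lo_n, hi_n] mapping to score 0 and extreme
## bounds [lo_e, hi_e] mapping to score 1 (linear in between, per side).
.vital_groups <- function() {
  vit <- list(
    list("blood pressure", 90, 120, 50, 200),
    list("pain score", 0, 1, -1, 10),
    list("pulse rate", 60, 100, 25, 190),
    list("body temperature", 36.1, 37.2, 32, 41.5),
    list("body mass index", 18.5, 25, 10, 50))
  mapply(function(i, v) {
    .mk_feature(55L + i, v[[1]], "vital", "graded",
                paste0("vital:", gsub(" ", "_", v[[1]])),
                meta = list(lo_n = v[[2]], hi_n = v[[3]],
                            lo_e = v[[4]], hi_e = v[[5]]))
  }, seq_along(vit), vit, SIMPLIFY = FALSE)
}

## 24 bipolar-disorder symptom groups with keyword lists drawn from standard
## instruments (HAM-D, YMRS, MADRS, PANSS, SAS/BARS/AIMS, C-SSRS).
.symptom_groups <- function() {
  sym <- list(
    depressed_mood = c("depressed", "depression", "sad mood", "hopeless",
                       "tearful"),
    anhedonia = c("anhedonia", "loss of interest", "no pleasure"),
    guilt = c("guilt", "guilty", "worthless", "self-blame"),
    suicidal_ideation = c("suicidal", "suicide", "self-harm", "wish to die"),
    insomnia = c("insomnia", "cannot sleep", "sleepless", "trouble sleeping"),
    hypersomnia = c("hypersomnia", "sleeping too much", "oversleeping"),
    decreased_need_for_sleep = c("decreased need for sleep",
                                 "little need for sleep",
                                 "rested after a few hours"),
    fatigue = c("fatigue", "fatigued", "low energy", "lethargy"),
    appetite_change = c("poor appetite", "appetite change", "weight loss",
                        "weight gain"),
    anxiety = c("anxiety", "anxious", "panic", "excessive worry"),
    agitation = c("agitation", "agitated", "restlessness"),
    irritability = c("irritable", "irritability", "short temper"),
    elevated_mood = c("euphoria", "euphoric", "elevated mood", "elated"),
    grandiosity = c("grandiose", "grandiosity", "inflated self-esteem"),
    racing_thoughts = c("racing thoughts", "flight of ideas",
                        "thoughts racing"),
    pressured_speech = c("pressured speech", "overly talkative",
                         "rapid speech"),
    distractibility = c("distractible", "distractibility", "poor attention"),
    increased_activity = c("increased activity", "hyperactive",
                           "psychomotor activation"),
    risky_behavior = c("risky behavior", "impulsive", "reckless",
                       "spending spree"),
    hallucinations = c("hallucination", "hallucinations", "hearing voices"),
    delusions = c("delusion", "delusions", "paranoid", "paranoia"),
    disorganized_thinking = c("disorganized", "incoherent",
                              "loose associations"),
    movement_symptoms = c("tremor", "akathisia", "rigidity", "dyskinesia"),
    poor_concentration = c("poor concentration", "cannot focus",
                           "inattentive"))
  mapply(function(i, n, kw) {
    .mk_feature(60L + i, n, "symptom", "binary", paste0("symptom:", n),
                meta = list(keywords = kw))
  }, seq_along(sym), names(sym), sym, SIMPLIFY = FALSE)
}

#' Default 84-row feature registry
#'
#' Builds the default schema of the temporal image y-axis: row 1 is
#' hospitalization; rows 2--22 the 21 mental-disorder diagnosis groups (ICD-9
#' 290--319 at three-digit detail); rows 23--38 the remaining ICD-9 chapter
#' groups in ascending code order (digestive system 520--579 lands on row 30);
#' rows 39--45 the seven CPT procedure groups; rows 46--55 the ten most
#' frequent labs (graded); rows 56--60 five vitals (graded); rows 61--84 the
#' 24 bipolar-disorder symptom keyword groups.
#'
#' The composition of rows not pinned by a published anchor is a documented
#' package convention; any alternative layout can be supplied via
#' \code{\link{loadRegistry}}.
#'
#' @return A \code{\linkS4class{FeatureRegistry}} with exactly 84 rows.
#' @examples
#' reg <- defaultRegistry()
#' nFeatures(reg)                       # 84
#' lookupFeature(reg, "540")$name       # digestive system, row 30
#' @export
defaultRegistry <- function() {
  feats <- c(
    list(.mk_feature(1L, "hospitalization", "hospitalization", "binary",
                     "hosp")),
    .mental_groups(), .other_dx_groups(), .procedure_groups(),
    .lab_groups(), .vital_groups(), .symptom_groups())
  reg <- .registry_from_list(feats, version = "default-84")
  .check_code_overlaps(reg)
  stopifnot(nrow(reg@features) == 84L)
  reg
}

#' @describeIn defaultRegistry Number of feature rows in a registry.
#' @param x A \code{FeatureRegistry}.
#' @export
setMethod("nFeatures", "FeatureRegistry", function(x) nrow(x@features))

#' Feature definitions as a data frame
#'
#' @param registry A \code{FeatureRegistry}.
#' @return A \code{data.frame} with one row per feature (codes collapsed with
#'   \code{";"}).
#' @export
featureTable <- function(registry) {
  ft <- registry@features
  data.frame(row = ft$row, name = ft$name, group = ft$group, kind = ft$kind,
             codes = vapply(ft$codes, paste, character(1), collapse = ";"),
             stringsAsFactors = FALSE)
}

## ---- code pattern parsing -------------------------------------------------

.parse_icd_range <- function(pat) {
  # "520-579", "290", "V01-V91", "E000-E999" -> list(system, lo, hi)
  m <- regmatches(pat, regexec("^([VE]?)([0-9]{1,3})(-([VE]?)([0-9]{1,3}))?$",
                               pat))[[1]]
  if (!length(m)) return(NULL)
  sys <- if (m[2] == "") "icd9" else paste0("icd9", m[2])
  lo <- as.integer(m[3])
  hi <- if (m[4] == "") lo else as.integer(m[6])
  list(system = sys, lo = lo, hi = hi)
}

.parse_pattern <- function(pat) {
  if (grepl("^cpt:", pat)) {
    r <- strsplit(sub("^cpt:", "", pat), "-", fixed = TRUE)[[1]]
    return(list(system = "cpt", lo = as.integer(r[1]),
                hi = as.integer(r[length(r)])))
  }
  if (grepl("^hcpcs:", pat)) {
    r <- strsplit(sub("^hcpcs:", "", pat), "-", fixed = TRUE)[[1]]
    return(list(system = "hcpcs", lo = r[1], hi = r[length(r)]))
  }
  if (grepl("^(lab|vital|symptom):", pat)) {
    p <- strsplit(pat, ":", fixed = TRUE)[[1]]
    return(list(system = p[1], name = tolower(p[2])))
  }
  if (pat %in% c("hosp", "hospitalization"))
    return(list(system = "hosp"))
  icd <- .parse_icd_range(pat)
  if (!is.null(icd)) return(icd)
  list(system = "name", name = tolower(pat))
}

## Exhaustive overlap check: within each code system, ranges must be disjoint
## and names unique.
.check_code_overlaps <- function(registry) {
  ft <- registry@features
  pats <- lapply(seq_len(nrow(ft)), function(i) {
    lapply(ft$codes[[i]], function(p) c(.parse_pattern(p), row = ft$row[i]))
  })
  pats <- unlist(pats, recursive = FALSE)
  sys <- vapply(pats, `[[`, character(1), "system")
  for (s in unique(sys)) {
    ps <- pats[sys == s]
    if (!is.null(ps[[1]]$lo) && is.numeric(ps[[1]]$lo)) {
      ord <- order(vapply(ps, `[[`, numeric(1), "lo"))
      ps <- ps[ord]
      if (length(ps) > 1) {
        lo <- vapply(ps, `[[`, numeric(1), "lo")
        hi <- vapply(ps, `[[`, numeric(1), "hi")
        if (any(lo[-1] <= hi[-length(hi)]))
          stop("overlapping code ranges in system '", s, "'")
      }
    } else if (!is.null(ps[[1]]$name)) {
      nm <- vapply(ps, `[[`, character(1), "name")
      if (anyDuplicated(nm))
        stop("duplicate code names in system '", s, "'")
    }
  }
  invisible(TRUE)
}

## ---- lookup ---------------------------------------------------------------

.classify_code <- function(code) {
  code <- trimws(code)
  if (grepl("^(lab|vital|symptom):", code)) {
    p <- strsplit(code, ":", fixed = TRUE)[[1]]
    return(list(system = p[1], key = tolower(gsub(" ", "_", p[2]))))
  }
  if (code %in% c("hosp", "hospitalization"))
    return(list(system = "hosp"))
  if (grepl("^[0-9]{5}$", code))
    return(list(system = "cpt", num = as.integer(code)))
  if (grepl("^[A-V][0-9]{4}$", code))
    return(list(system = "hcpcs", letter = substr(code, 1, 1)))
  if (grepl("^[0-9]{3}(\\.[0-9]*)?$", code))
    return(list(system = "icd9", num = as.integer(substr(code, 1, 3))))
  if (grepl("^[VE][0-9]+(\\.[0-9]*)?$", code))
    return(list(system = paste0("icd9", substr(code, 1, 1)),
                num = as.integer(sub("^[VE]", "", sub("\\..*$", "", code)))))
  list(system = "name", key = tolower(gsub(" ", "_", code)))
}

#' Resolve a source code to its owning feature
#'
#' ICD-9 diagnosis codes (e.g. \code{"296.4"}, \code{"V70"}) match by the
#' range of their integer part; 5-digit CPT codes by numeric range; HCPCS
#' level II codes by their letter prefix; labs, vitals and symptom groups by
#' (optionally prefixed) name, e.g. \code{"glucose"} or \code{"lab:glucose"}.
#'
#' @param registry A \code{\linkS4class{FeatureRegistry}}.
#' @param code A single source code.
#' @return A list with the feature's \code{row}, \code{name}, \code{group},
#'   \code{kind} and \code{meta}, or an error of class
#'   \code{"phenoprint_unknown_code"} if no row owns the code.
#' @examples
#' reg <- defaultRegistry()
#' lookupFeature(reg, "540")$row        # 30 (digestive system, 520-579)
#' lookupFeature(reg, "glucose")$kind   # "graded"
#' @export
lookupFeature <- function(registry, code) {
  ft <- registry@features
  cl <- .classify_code(code)
  for (i in seq_len(nrow(ft))) {
    for (p in ft$codes[[i]]) {
      pp <- .parse_pattern(p)
      hit <- switch(cl$system,
        hosp  = identical(pp$system, "hosp"),
        cpt   = identical(pp$system, "cpt") &&
                cl$num >= pp$lo && cl$num <= pp$hi,
        hcpcs = identical(pp$system, "hcpcs") &&
                cl$letter >= pp$lo && cl$letter <= pp$hi,
        icd9  = identical(pp$system, "icd9") &&
                cl$num >= pp$lo && cl$num <= pp$hi,
        icd9V = identical(pp$system, "icd9V") &&
                cl$num >= pp$lo && cl$num <= pp$hi,
        icd9E = identical(pp$system, "icd9E") &&
                cl$num >= pp$lo && cl$num <= pp$hi,
        # name-like code: match lab/vital/symptom names or bare feature name
        (pp$system %in% c("lab", "vital", "symptom") &&
           identical(gsub(" ", "_", pp$name), cl$key)) ||
          identical(tolower(gsub(" ", "_", ft$name[i])), cl$key))
      if (isTRUE(hit))
        return(list(row = ft$row[i], name = ft$name[i], group = ft$group[i],
                    kind = ft$kind[i], meta = ft$meta[[i]]))
    }
  }
  stop(structure(class = c("phenoprint_unknown_code", "error", "condition"),
                 list(message = paste0("unknown code: '", code, "'"),
                      call = sys.call(-1))))
}

#' A concrete example code owned by a feature row
#'
#' Used by the synthetic generator to emit events that resolve back to a given
#' row (e.g. the start of an ICD range, or the lab name).
#'
#' @param registry A \code{FeatureRegistry}.
#' @param row A feature row index present in the registry.
#' @return A single character code.
#' @export
representativeCode <- function(registry, row) {
  ft <- registry@features
  i <- match(row, ft$row)
  if (is.na(i)) stop("row ", row, " not in registry")
  p <- .parse_pattern(ft$codes[[i]][1])
  switch(p$system,
    hosp  = "hosp",
    cpt   = sprintf("%05d", p$lo),
    hcpcs = paste0(p$lo, "0001"),
    icd9  = sprintf("%03d", p$lo),
    icd9V = sprintf("V%02d", p$lo),
    icd9E = sprintf("E%03d", p$lo),
    lab   = paste0("lab:", gsub(" ", "_", p$name)),
    vital = paste0("vital:", gsub(" ", "_", p$name)),
    symptom = paste0("symptom:", p$name),
    ft$name[i])
}

## ---- YAML serialization ---------------------------------------------------

#' Write a feature registry to a YAML file
#'
#' @param registry A \code{FeatureRegistry}.
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @seealso \code{\link{loadRegistry}}
#' @export
writeRegistry <- function(registry, path) {
  ft <- registry@features
  feats <- lapply(seq_len(nrow(ft)), function(i) {
    f <- list(row = ft$row[i], name = ft$name[i], group = ft$group[i],
              kind = ft$kind[i], codes = as.list(ft$codes[[i]]))
    if (length(ft$meta[[i]])) f$meta <- ft$meta[[i]]
    f
  })
  yaml::write_yaml(list(version = registry@version, features = feats), path)
  invisible(path)
}

#' Load a feature registry from a YAML file
#'
#' Validates the schema on load: duplicate row indices and overlapping code
#' ranges are errors; a registry without exactly 84 rows is rejected unless
#' \code{allow_partial = TRUE} (images then take the registry's own row
#' count).
#'
#' @param path YAML file written by \code{\link{writeRegistry}} (schema: a
#'   \code{version} string and a \code{features} list with \code{row},
#'   \code{name}, \code{group}, \code{kind}, \code{codes}, optional
#'   \code{meta}).
#' @param allow_partial Allow a registry with a row count other than 84.
#' @return A \code{\linkS4class{FeatureRegistry}}.
#' @export
loadRegistry <- function(path, allow_partial = FALSE) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw$features))
    stop("registry file has no 'features' entry")
  feats <- lapply(raw$features, function(f) {
    .mk_feature(f$row, f$name, f$group, f$kind,
                unlist(f$codes, use.names = FALSE),
                meta = if (is.null(f$meta)) list() else f$meta)
  })
  rows <- vapply(feats, `[[`, integer(1), "row")
  if (anyDuplicated(rows))
    stop("duplicate row indices in registry file: ",
         paste(unique(rows[duplicated(rows)]), collapse = ", "))
  reg <- .registry_from_list(feats,
                             version = if (is.null(raw$version)) "custom"
                                       else raw$version)
  .check_code_overlaps(reg)
  n <- nrow(reg@features)
  if (n != 84L && !allow_partial)
    stop("registry has ", n, " rows, not 84; pass allow_partial = TRUE ",
         "to accept a non-standard schema")
  if (n != 84L)
    warning("non-standard registry with ", n, " rows; temporal images will ",
            "be ", n, " x 53")
  if (!identical(sort(reg@features$row), seq_len(n)))
    stop("row indices must be a permutation of 1..", n)
  reg
}
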