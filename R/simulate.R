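# Deterministic synthetic multi-study project generator.  Emits a project
# metadata document, SDTM-dialect clinical CSVs per study, ISA-style
# sample/feature/measurement triplets per assay, a loading plan and a
# ground-truth manifest.  Each file draws from its own pseudo-random
# stream, derived from (seed, file name), so adding a study or assay to a
# config never perturbs the other files.

set_file_seed <- function(seed, filename)
  set.seed((as.integer(seed) + hash_string(filename)) %% 2147483647L)

#' Synthetic project generator configuration
#'
#' @param seed integer; together with the config it fully determines every
#'   generated byte.
#' @param project_id,kind,title project metadata.
#' @param studies list of study specs:
#'   `list(study_id, n_subjects, arms, visits)` where `visits` is a data
#'   frame with `label` and `day`.
#' @param domains list of clinical domain specs.  A findings domain:
#'   `list(domain, activity, template, kind = "finding", vars = list(
#'   list(code, label, unit, mu, sigma, lo, hi, valid, digits)))` — values
#'   are drawn from a normal distribution truncated (clamped) to
#'   `[lo, hi]`; `valid` is the plausibility range enforced at load.  An
#'   events domain: `kind = "event"`, `terms = list(list(code, label, p))`
#'   with per-subject occurrence probability `p` and a severity drawn from
#'   MILD/MODERATE/SEVERE.  Domains are shared by all studies unless
#'   `studies` names a subset — shared variables are what the warehouse
#'   harmonizes across studies.
#' @param assays list of assay specs: `list(activity, technology
#'   ("MA"/"CYT"/"FACS"), n_features, subjects_per_study,
#'   samples_per_subject, mu, sigma, missing_rate)`.
#' @param missing_rate probability that an optional clinical field
#'   (collection date) is blank.
#' @param inject optional deliberate-violation spec:
#'   `list(range = n, vocab = n, duplicate = n)`, applied to the first
#'   findings file of the first study; the manifest ledger records the
#'   expected issue counts and the plan marks the file as expected to
#'   fail.
#' @return A `tm_genconfig` list.
#' @export
generator_config <- function(seed, project_id, kind, title, studies, domains,
                             assays = list(), missing_rate = 0,
                             inject = NULL) {
  for (d in domains) {
    if ((d$kind %||% "finding") == "event") {
      p <- vapply(d$terms, function(t) t$p, 0)
      if (any(p < 0 | p > 1)) tm_stop("event probabilities must be in [0,1]")
    } else {
      for (v in d$vars)
        if (v$lo < v$valid[1] || v$hi > v$valid[2])
          tm_stop(sprintf(
            "infeasible config: %s/%s draws in [%g,%g] outside its valid range [%g,%g]",
            d$domain, v$code, v$lo, v$hi, v$valid[1], v$valid[2]))
    }
    extra <- setdiff(d$studies %||% character(),
                     vapply(studies, `[[`, "", "study_id"))
    if (length(extra))
      tm_stop(sprintf("domain '%s' names unknown study: %s", d$domain,
                      paste(extra, collapse = ", ")))
  }
  structure(list(seed = as.integer(seed), project_id = project_id,
                 kind = kind, title = title, studies = studies,
                 domains = domains, assays = assays,
                 missing_rate = missing_rate, inject = inject),
            class = "tm_genconfig")
}

gen_dm <- function(cfg, st) {
  fname <- paste0(st$study_id, "_DM.csv")
  set_file_seed(cfg$seed, fname)
  n <- st$n_subjects
  subj <- sprintf("%s-%04d", st$study_id, seq_len(n))
  data.frame(STUDYID = st$study_id, USUBJID = subj,
             AGE = sample(18:80, n, replace = TRUE),
             SEX = sample(c("M", "F"), n, replace = TRUE),
             ARMCD = sample(st$arms, n, replace = TRUE),
             COUNTRY = sample(c("GBR", "DEU", "ITA", "FRA"), n,
                              replace = TRUE),
             stringsAsFactors = FALSE)
}

sdtm_prefix <- function(template) if (template == "LB") "LB" else "VS"

gen_finding <- function(cfg, st, dom) {
  fname <- paste0(st$study_id, "_", dom$domain, ".csv")
  set_file_seed(cfg$seed, fname)
  subj <- sprintf("%s-%04d", st$study_id, seq_len(st$n_subjects))
  visits <- dom$visit_labels %||% st$visits$label
  grid <- expand.grid(USUBJID = subj, VISIT = visits,
                      var = seq_along(dom$vars), stringsAsFactors = FALSE,
                      KEEP.OUT.ATTRS = FALSE)
  grid <- grid[order(grid$USUBJID, grid$var, grid$VISIT), , drop = FALSE]
  vcode <- vapply(dom$vars, `[[`, "", "code")
  vlab <- vapply(dom$vars, `[[`, "", "label")
  vunit <- vapply(dom$vars, `[[`, "", "unit")
  mu <- vapply(dom$vars, function(v) v$mu, 0)
  sg <- vapply(dom$vars, function(v) v$sigma, 0)
  lo <- vapply(dom$vars, function(v) v$lo, 0)
  hi <- vapply(dom$vars, function(v) v$hi, 0)
  dg <- vapply(dom$vars, function(v) as.integer(v$digits %||% 1L), 0L)
  i <- grid$var
  val <- pmin(pmax(stats::rnorm(nrow(grid), mu[i], sg[i]), lo[i]), hi[i])
  val <- round(val, dg[i])
  date <- format(as.Date("2016-01-04") +
                   sample(0:120, nrow(grid), replace = TRUE))
  if (cfg$missing_rate > 0)
    date[stats::runif(nrow(grid)) < cfg$missing_rate] <- ""
  pre <- sdtm_prefix(dom$template)
  out <- data.frame(STUDYID = st$study_id, USUBJID = grid$USUBJID,
                    TESTCD = vcode[i], TEST = vlab[i],
                    ORRES = format(val, trim = TRUE, scientific = FALSE),
                    ORRESU = vunit[i], DTC = date, VISIT = grid$VISIT,
                    stringsAsFactors = FALSE)
  names(out) <- c("STUDYID", "USUBJID", paste0(pre, "TESTCD"),
                  paste0(pre, "TEST"), paste0(pre, "ORRES"),
                  paste0(pre, "ORRESU"), paste0(pre, "DTC"), "VISIT")
  out
}

gen_event <- function(cfg, st, dom) {
  fname <- paste0(st$study_id, "_", dom$domain, ".csv")
  set_file_seed(cfg$seed, fname)
  subj <- sprintf("%s-%04d", st$study_id, seq_len(st$n_subjects))
  rows <- list()
  for (t in dom$terms) {
    hit <- stats::runif(length(subj)) < t$p
    if (!any(hit)) next
    rows[[t$code]] <- data.frame(
      STUDYID = st$study_id, USUBJID = subj[hit], AETERM = t$label,
      AEDECOD = t$code,
      AESEV = sample(c("MILD", "MODERATE", "SEVERE"), sum(hit),
                     replace = TRUE, prob = c(0.5, 0.35, 0.15)),
      AESTDTC = format(as.Date("2016-01-04") +
                         sample(0:120, sum(hit), replace = TRUE)),
      stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(STUDYID = character(), USUBJID = character(),
                      AETERM = character(), AEDECOD = character(),
                      AESEV = character(), AESTDTC = character(),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  out[order(out$USUBJID, out$AETERM), , drop = FALSE]
}

gen_assay <- function(cfg, assay) {
  tech <- assay$technology
  sample_rows <- list()
  for (st in cfg$studies) {
    if (!is.null(assay$studies) && !st$study_id %in% assay$studies) next
    fname <- paste0(assay$activity, "_", st$study_id, "_samples")
    set_file_seed(cfg$seed, fname)
    nsub <- min(assay$subjects_per_study, st$n_subjects)
    picked <- sort(sample(seq_len(st$n_subjects), nsub))
    subj <- sprintf("%s-%04d", st$study_id, picked)
    k <- assay$samples_per_subject %||% 1L
    visits <- st$visits$label[seq_len(min(k, nrow(st$visits)))]
    for (j in seq_len(k)) {
      sample_rows[[paste(st$study_id, j)]] <- data.frame(
        STUDYID = st$study_id,
        SAMPLEID = sprintf("%s-%s-%04d-%d", st$study_id, tech, picked, j),
        USUBJID = subj,
        SPECTYPE = assay$specimen %||% "whole blood",
        VISIT = visits[min(j, length(visits))], stringsAsFactors = FALSE)
    }
  }
  samples <- do.call(rbind, sample_rows)
  samples <- samples[order(samples$SAMPLEID), , drop = FALSE]
  feats <- data.frame(
    FEATUREID = sprintf("%s_F%04d", tech, seq_len(assay$n_features)),
    SYMBOL = sprintf("G%04d", seq_len(assay$n_features)),
    NAME = sprintf("%s feature %d", tech, seq_len(assay$n_features)),
    stringsAsFactors = FALSE)
  fname <- paste0(assay$activity, "_MEASUREMENT")
  set_file_seed(cfg$seed, fname)
  mat <- matrix(stats::rnorm(assay$n_features * nrow(samples),
                             assay$mu %||% 8, assay$sigma %||% 2),
                nrow = assay$n_features)
  mat <- round(mat, 3)
  cells <- format(mat, trim = TRUE, scientific = FALSE)
  mr <- assay$missing_rate %||% 0
  if (mr > 0) cells[stats::runif(length(cells)) < mr] <- ""
  meas <- data.frame(FEATUREID = feats$FEATUREID, cells,
                     stringsAsFactors = FALSE, check.names = FALSE)
  names(meas) <- c("FEATUREID", samples$SAMPLEID)
  list(samples = samples, features = feats, measurement = meas)
}

domain_studies <- function(cfg, dom)
  dom$studies %||% vapply(cfg$studies, `[[`, "", "study_id")

inject_errors <- function(cfg, df, dom) {
  inj <- cfg$inject
  pre <- sdtm_prefix(dom$template)
  counts <- c(RANGE_VIOLATION = 0L, VOCAB_VIOLATION = 0L, DUPLICATE_KEY = 0L)
  hi <- max(vapply(dom$vars, function(v) v$valid[2], 0))
  set_file_seed(cfg$seed, "injection")
  touched <- integer()
  inj <- lapply(inj, as.integer)
  n_range <- inj$range %||% 0L
  if (n_range > 0) {
    rows <- sample(nrow(df), n_range)
    df[[paste0(pre, "ORRES")]][rows] <- format(hi + 1000 + seq_len(n_range))
    counts["RANGE_VIOLATION"] <- n_range
    touched <- union(touched, rows)
  }
  n_vocab <- inj$vocab %||% 0L
  if (n_vocab > 0) {
    rows <- sample(setdiff(seq_len(nrow(df)), touched), n_vocab)
    df[[paste0(pre, "TESTCD")]][rows] <- "ZZZZ"
    counts["VOCAB_VIOLATION"] <- n_vocab
    touched <- union(touched, rows)
  }
  n_dup <- inj$duplicate %||% 0L
  if (n_dup > 0) {
    rows <- sample(setdiff(seq_len(nrow(df)), touched), n_dup)
    df <- rbind(df, df[rows, , drop = FALSE])
    counts["DUPLICATE_KEY"] <- n_dup
  }
  list(df = df, counts = counts[counts > 0])
}

#' Generate a synthetic multi-study project on disk
#'
#' Writes `project.json` (project graph plus an ordered loading plan),
#' one DM and one file per clinical domain per study, ISA-style triplets
#' per assay, and `manifest.json` with the ground truth an end-to-end load
#' must recover.  The same seed and config produce byte-identical output.
#'
#' @param config a [generator_config()] or preset.
#' @param out_dir output directory (created).
#' @return The manifest, invisibly.
#' @export
generate_project <- function(config, out_dir) {
  stopifnot(inherits(config, "tm_genconfig"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  plan <- list()
  obs_per_dataset <- list()
  injected <- list()
  feat_keys <- character()
  n_samples <- 0L
  n_assay_events <- 0L
  mol_keys <- character()

  write_clin <- function(df, fname)
    utils::write.csv(df, file.path(out_dir, fname), row.names = FALSE,
                     quote = TRUE)
  write_isa <- function(df, fname)
    utils::write.table(df, file.path(out_dir, fname), sep = "\t",
                       row.names = FALSE, qmethod = "double")

  for (st in config$studies) {
    fname <- paste0(st$study_id, "_DM.csv")
    write_clin(gen_dm(config, st), fname)
    plan[[length(plan) + 1L]] <- list(
      file = fname, template = "DM", domain = "DM",
      activity = config$domains[[1]]$activity, study_id = st$study_id)
  }

  first_finding <- TRUE
  for (dom in config$domains) {
    kind <- dom$kind %||% "finding"
    pre <- if (kind == "finding") sdtm_prefix(dom$template) else "AE"
    for (sid in domain_studies(config, dom)) {
      st <- config$studies[[match(sid, vapply(config$studies, `[[`, "",
                                              "study_id"))]]
      fname <- paste0(sid, "_", dom$domain, ".csv")
      df <- if (kind == "finding") gen_finding(config, st, dom)
            else gen_event(config, st, dom)
      expect_fail <- FALSE
      if (kind == "finding" && first_finding && !is.null(config$inject)) {
        res <- inject_errors(config, df, dom)
        df <- res$df
        injected[[fname]] <- as.list(res$counts)
        expect_fail <- length(res$counts) > 0
        first_finding <- FALSE
      }
      write_clin(df, fname)
      step <- list(file = fname, template = dom$template,
                   domain = dom$domain, activity = dom$activity,
                   study_id = sid, expect_fail = expect_fail)
      if (kind == "finding") {
        step$vocab <- stats::setNames(
          list(vapply(dom$vars, `[[`, "", "code")), paste0(pre, "TESTCD"))
        rng <- range(unlist(lapply(dom$vars, function(v) v$valid)))
        step$element <- list(field = paste0(pre, "ORRES"),
                             concept = paste(dom$domain, "result"),
                             datatype = "decimal", range = rng)
      }
      plan[[length(plan) + 1L]] <- step
      if (!expect_fail) {
        obs_per_dataset[[fname]] <- nrow(df)
        if (kind == "finding") {
          keys <- feature_key("finding", dom$domain,
                              vapply(dom$vars, `[[`, "", "code"),
                              vapply(dom$vars, `[[`, "", "unit"))
          feat_keys <- union(feat_keys, keys)
        } else if (nrow(df)) {
          keys <- feature_key("event", dom$domain, unique(df$AETERM))
          feat_keys <- union(feat_keys, keys)
        }
      }
    }
  }

  for (assay in config$assays) {
    parts <- gen_assay(config, assay)
    s_f <- paste0(assay$activity, "_SAMPLE.tsv")
    f_f <- paste0(assay$activity, "_FEATURE.tsv")
    m_f <- paste0(assay$activity, "_MEASUREMENT.tsv")
    write_isa(parts$samples, s_f)
    write_isa(parts$features, f_f)
    write_isa(parts$measurement, m_f)
    tech <- assay$technology
    plan[[length(plan) + 1L]] <- list(file = s_f, template = "SAMPLE",
                                      domain = "SAMPLE",
                                      activity = assay$activity)
    plan[[length(plan) + 1L]] <- list(file = f_f, template = "FEATURE",
                                      domain = "FEATURE",
                                      activity = assay$activity)
    plan[[length(plan) + 1L]] <- list(
      file = m_f, template = paste0("MEASUREMENT-", tech), domain = tech,
      activity = assay$activity)
    n_samples <- n_samples + nrow(parts$samples)
    cells <- as.matrix(parts$measurement[-1])
    live <- cells != ""
    obs_per_dataset[[m_f]] <- sum(live)
    n_assay_events <- n_assay_events + sum(colSums(live) > 0)
    mol_keys <- union(mol_keys,
                      feature_key("molecular", tech,
                                  parts$features$FEATUREID))
  }

  manifest <- list(
    subjects = as.integer(sum(vapply(config$studies,
                                     function(s) s$n_subjects, 0))),
    samples = as.integer(n_samples),
    assays = as.integer(n_assay_events),
    clinical_features = length(feat_keys),
    molecular_features = length(mol_keys),
    observations = as.integer(sum(unlist(obs_per_dataset))),
    observations_per_dataset = lapply(obs_per_dataset, as.integer),
    injected = injected)

  project_doc <- list(
    format_version = 1L,
    project_id = config$project_id, kind = config$kind,
    title = config$title,
    studies = lapply(config$studies, function(s)
      list(study_id = s$study_id, arms = s$arms,
           visits = list(label = s$visits$label, day = s$visits$day))),
    activities = c(
      lapply(split(config$domains,
                   vapply(config$domains, `[[`, "", "activity")), function(g)
        list(activity_id = g[[1]]$activity, kind = "clinical-assessment",
             name = g[[1]]$activity)),
      lapply(config$assays, function(a)
        list(activity_id = a$activity, kind = "molecular-assay",
             name = a$activity, technology = a$technology))),
    plan = plan)
  jsonlite::write_json(project_doc, file.path(out_dir, "project.json"),
                       auto_unbox = TRUE, null = "null", digits = NA,
                       pretty = TRUE)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, null = "null", digits = NA,
                       pretty = TRUE)
  invisible(manifest)
}

#' Load a generated project end to end
#'
#' Reads the project document and loading plan written by
#' [generate_project()], builds the project graph, registers customized
#' descriptors (vocabularies on test codes, plausibility-range elements on
#' results), uploads and loads every file in plan order, and returns the
#' project together with the per-file load results and the manifest.
#'
#' @param dir a directory written by [generate_project()].
#' @param user acting user recorded in the audit trail.
#' @return A list with `project`, `results` (per-file status and report)
#'   and `manifest`.
#' @export
ingest_simulated <- function(dir, user = "generator") {
  doc <- jsonlite::fromJSON(file.path(dir, "project.json"),
                            simplifyVector = FALSE)
  manifest <- jsonlite::fromJSON(file.path(dir, "manifest.json"),
                                 simplifyVector = TRUE)
  project <- create_project(doc$kind, doc$title, doc$project_id)
  for (s in doc$studies)
    add_study(project, study(
      s$study_id, arms = unlist(s$arms),
      visits = data.frame(label = unlist(s$visits$label),
                          day = unlist(s$visits$day))))
  for (a in doc$activities)
    add_activity(project, activity(a$activity_id, a$kind, a$name,
                                   technology = a$technology))
  reg <- element_registry()
  results <- list()
  for (step in doc$plan) {
    d <- get_template(step$template)
    if (!identical(step$domain, d$domain_code)) d$domain_code <- step$domain
    d$descriptor_id <- paste0("d-", step$file)
    if (!is.null(step$vocab))
      for (fn in names(step$vocab))
        d <- customize(d, set_vocabulary(fn, unlist(step$vocab[[fn]])))
    if (!is.null(step$element)) {
      el <- tryCatch(
        define_data_element(reg, step$element$concept,
                            value_domain("continuous",
                                         datatype = step$element$datatype,
                                         range = unlist(step$element$range))),
        custodian_conflict = function(e) NULL)
      if (is.null(el)) {
        existing <- Filter(function(x)
          x$concept_label == step$element$concept, reg$elements)
        el <- existing[[1]]
      }
      d <- customize(d, bind_element(step$element$field, el))
    }
    register_descriptor(project, step$activity, d)
    fid <- upload_file(project, file.path(dir, step$file), user)
    results[[step$file]] <- load_dataset(project, fid, d$descriptor_id,
                                         user, study_id = step$study_id)
  }
  list(project = project, results = results, manifest = manifest)
}

# ---- presets ------------------------------------------------------------

finding_vars <- function(prefix, n, unit, mu, sigma, spread, valid) {
  lapply(seq_len(n), function(i)
    list(code = sprintf("%s%02d", prefix, i),
         label = sprintf("%s test %02d", prefix, i), unit = unit,
         mu = mu + i, sigma = sigma, lo = mu + i - spread,
         hi = mu + i + spread, valid = valid, digits = 1L))
}

#' Shipped generator presets
#'
#' `preset_tiny()` is a two-study project small enough for unit tests
#' (5 subjects per study, LB + VS + AE plus one expression assay).
#' `preset_ers_like()` emulates the shape of a meta-study respiratory
#' pilot: two independent studies totalling 1,294 subjects, four
#' findings-class clinical activities (laboratory tests, vital signs,
#' spirometry, reversibility) whose 39 variables are shared by both
#' studies, and one gene-expression assay.  `preset_biovacsafe_like()`
#' emulates a multi-study vaccine-trial programme: five studies covering
#' seven arms, DM/LB/VS/AE clinical data and three assay types
#' (expression, cytokine panel, flow cytometry).
#'
#' @param seed integer seed; the default is part of the preset.
#' @param inject optional violation-injection spec passed to
#'   [generator_config()].
#' @return A `tm_genconfig`.
#' @export
preset_tiny <- function(seed = 101L, inject = NULL) {
  studies <- list(
    list(study_id = "S1", n_subjects = 5L, arms = c("A", "B"),
         visits = data.frame(label = c("V1", "V2"), day = c(1, 8))),
    list(study_id = "S2", n_subjects = 5L, arms = c("A", "B"),
         visits = data.frame(label = c("V1", "V2"), day = c(1, 8))))
  domains <- list(
    list(domain = "LB", activity = "lab-tests", template = "LB",
         kind = "finding",
         vars = list(
           list(code = "ALB", label = "Albumin", unit = "g/dL", mu = 4.2,
                sigma = 0.4, lo = 2.5, hi = 5.8, valid = c(0, 10),
                digits = 1L),
           list(code = "GLUC", label = "Glucose", unit = "mmol/L", mu = 5.5,
                sigma = 0.9, lo = 3, hi = 10, valid = c(0, 30),
                digits = 1L),
           list(code = "CREAT", label = "Creatinine", unit = "umol/L",
                mu = 80, sigma = 15, lo = 40, hi = 140, valid = c(0, 400),
                digits = 0L))),
    list(domain = "VS", activity = "vital-signs", template = "VS",
         kind = "finding",
         vars = list(
           list(code = "SYSBP", label = "Systolic blood pressure",
                unit = "mmHg", mu = 122, sigma = 14, lo = 85, hi = 185,
                valid = c(40, 300), digits = 0L),
           list(code = "DIABP", label = "Diastolic blood pressure",
                unit = "mmHg", mu = 78, sigma = 10, lo = 50, hi = 115,
                valid = c(20, 200), digits = 0L))),
    list(domain = "AE", activity = "vital-signs", template = "AE",
         kind = "event",
         terms = list(
           list(code = "HEADACHE", label = "Headache", p = 0.6),
           list(code = "FATIGUE", label = "Fatigue", p = 0.4))))
  assays <- list(list(activity = "expression", technology = "MA",
                      n_features = 4L, subjects_per_study = 2L,
                      samples_per_subject = 1L, mu = 8, sigma = 2,
                      missing_rate = 0))
  generator_config(seed, "tiny-project", "meta-study", "Tiny test project",
                   studies, domains, assays, missing_rate = 0.1,
                   inject = inject)
}

#' @rdname preset_tiny
#' @export
preset_ers_like <- function(seed = 2019L, inject = NULL) {
  studies <- list(
    list(study_id = "ASTH", n_subjects = 647L, arms = c("SEVERE", "MILD"),
         visits = data.frame(label = "V1", day = 1)),
    list(study_id = "COPD", n_subjects = 647L, arms = c("EMPH", "AIRW"),
         visits = data.frame(label = "V1", day = 1)))
  domains <- list(
    list(domain = "LB", activity = "lab-tests", template = "LB",
         kind = "finding",
         vars = finding_vars("LBT", 20L, "U/L", 40, 6, 25, c(0, 500))),
    list(domain = "VS", activity = "vital-signs", template = "VS",
         kind = "finding",
         vars = finding_vars("VST", 6L, "mmHg", 90, 12, 45, c(0, 400))),
    list(domain = "SP", activity = "spirometry", template = "VS",
         kind = "finding",
         vars = finding_vars("SPT", 8L, "L", 3, 0.8, 2.5, c(0, 30))),
    list(domain = "RV", activity = "reversibility", template = "VS",
         kind = "finding",
         vars = finding_vars("RVT", 5L, "percent", 12, 5, 11, c(-50, 100))))
  assays <- list(list(activity = "gene-expression", technology = "MA",
                      n_features = 30L, subjects_per_study = 20L,
                      samples_per_subject = 1L, mu = 8, sigma = 2,
                      missing_rate = 0))
  generator_config(seed, "ers-like-pilot", "meta-study",
                   "Respiratory meta-study pilot (synthetic)", studies,
                   domains, assays, missing_rate = 0.05, inject = inject)
}

#' @rdname preset_tiny
#' @export
preset_biovacsafe_like <- function(seed = 2020L, inject = NULL) {
  arms_by_study <- list(c("FLUAD", "AGRIPPAL"), c("STAMARIL", "VARILRIX"),
                        "BOOSTRIX", "ENGERIX", "PLACEBO")
  studies <- lapply(seq_len(5), function(i)
    list(study_id = paste0("VAC", i), n_subjects = 24L,
         arms = arms_by_study[[i]],
         visits = data.frame(label = c("D0", "D1", "D7"),
                             day = c(0, 1, 7))))
  domains <- list(
    list(domain = "LB", activity = "lab-tests", template = "LB",
         kind = "finding",
         vars = finding_vars("HEM", 5L, "x10^9/L", 6, 1.2, 4.5, c(0, 60))),
    list(domain = "VS", activity = "vital-signs", template = "VS",
         kind = "finding",
         vars = finding_vars("VIT", 4L, "mmHg", 85, 11, 40, c(0, 400))),
    list(domain = "AE", activity = "vital-signs", template = "AE",
         kind = "event",
         terms = list(
           list(code = "INJPAIN", label = "Injection site pain", p = 0.5),
           list(code = "PYREXIA", label = "Pyrexia", p = 0.2),
           list(code = "MYALGIA", label = "Myalgia", p = 0.3))))
  assays <- list(
    list(activity = "expression", technology = "MA", n_features = 20L,
         subjects_per_study = 6L, samples_per_subject = 2L, mu = 8,
         sigma = 2, missing_rate = 0.02),
    list(activity = "cytokines", technology = "CYT", n_features = 8L,
         subjects_per_study = 6L, samples_per_subject = 1L, mu = 50,
         sigma = 18, missing_rate = 0),
    list(activity = "facs", technology = "FACS", n_features = 6L,
         subjects_per_study = 4L, samples_per_subject = 1L, mu = 30,
         sigma = 9, missing_rate = 0))
  generator_config(seed, "vaccine-programme", "multi-study",
                   "Vaccine reactogenicity programme (synthetic)", studies,
                   domains, assays, missing_rate = 0.05, inject = inject)
}
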