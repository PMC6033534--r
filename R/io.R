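#' Read a study from a directory of CSV files
#'
#' Expects `saliva.csv` (subject_id, time_days, enrichment), `label.csv`
#' (subject_id, lineage, population, time_days, fraction_labelled), and
#' optionally `telomere.csv` (subject_id, lineage, theta_bp, sd_bp),
#' `yfv.csv` (subject_id, years_post_vaccination, frequency) and
#' `ground_truth.json`.  All files use comma-separated UTF-8 with `.` as
#' the decimal mark.  Schema violations are reported with file, row and
#' column.
#'
#' @param dir Directory path.
#' @return A list of class `tscm_study` (with `truth = NULL` unless a
#'   ground-truth file is present; missing optional datasets are `NULL`).
#' @export
read_study <- function(dir) {
  read_req <- function(file, cols) {
    path <- file.path(dir, file)
    if (!file.exists(path)) abort(paste0("missing required file: ", path))
    d <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
    miss <- setdiff(cols, names(d))
    if (length(miss)) {
      abort(sprintf("%s: missing column(s) %s", file, paste(miss, collapse = ", ")))
    }
    d
  }
  check_col <- function(d, file, col, ok, what) {
    bad <- which(!ok(d[[col]]))
    if (length(bad)) {
      abort(sprintf("%s: row %d, column '%s': %s", file, bad[1], col, what))
    }
  }
  saliva <- read_req("saliva.csv", c("subject_id", "time_days", "enrichment"))
  check_col(saliva, "saliva.csv", "time_days", function(x) x >= 0,
            "time must be non-negative")
  check_col(saliva, "saliva.csv", "enrichment",
            function(x) x >= 0 & x <= 1, "enrichment must lie in [0, 1]")

  label <- read_req("label.csv", c("subject_id", "lineage", "population",
                                   "time_days", "fraction_labelled"))
  check_col(label, "label.csv", "time_days", function(x) x >= 0,
            "time must be non-negative")
  check_col(label, "label.csv", "population",
            function(x) x %in% c("naive", "tscm"),
            "population must be 'naive' or 'tscm'")
  check_col(label, "label.csv", "fraction_labelled", function(x) x >= 0,
            "fraction must be non-negative")
  label |>
    dplyr::group_by(.data$subject_id, .data$lineage, .data$population) |>
    dplyr::group_walk(function(d, key) {
      if (is.unsorted(d$time_days)) {
        abort(sprintf("label.csv: non-ascending times for subject %s %s %s",
                      key$subject_id, key$lineage, key$population))
      }
    })

  telomere <- NULL
  if (file.exists(file.path(dir, "telomere.csv"))) {
    telomere <- read_req("telomere.csv", c("subject_id", "lineage", "theta_bp"))
  }
  yfv <- NULL
  if (file.exists(file.path(dir, "yfv.csv"))) {
    yfv <- read_req("yfv.csv", c("subject_id", "years_post_vaccination",
                                 "frequency"))
    check_col(yfv, "yfv.csv", "years_post_vaccination", function(x) x > 0,
              "time since vaccination must be positive")
    check_col(yfv, "yfv.csv", "frequency", function(x) x >= 0,
              "frequency must be non-negative")
  }
  truth <- NULL
  gt_path <- file.path(dir, "ground_truth.json")
  if (file.exists(gt_path)) truth <- truth_from_json(gt_path)

  structure(
    list(saliva = saliva, label = label, telomere = telomere, yfv = yfv,
         truth = truth,
         design = study_design(
           n_subjects = length(unique(saliva$subject_id)),
           label_times = sort(unique(label$time_days)),
           saliva_times = sort(unique(saliva$time_days)),
           lineages = unique(label$lineage)
         )),
    class = "tscm_study"
  )
}

#' Write a study to a directory of CSV files
#'
#' Inverse of [read_study()]; the ground truth, when present, is written as
#' `ground_truth.json` (clearly a synthetic-study artefact, never measured
#' data).
#'
#' @param study A `tscm_study`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(study$saliva, file.path(dir, "saliva.csv"), progress = FALSE)
  readr::write_csv(study$label, file.path(dir, "label.csv"), progress = FALSE)
  if (!is.null(study$telomere)) {
    readr::write_csv(study$telomere, file.path(dir, "telomere.csv"), progress = FALSE)
  }
  if (!is.null(study$yfv)) {
    readr::write_csv(study$yfv, file.path(dir, "yfv.csv"), progress = FALSE)
  }
  if (!is.null(study$truth)) {
    jsonlite::write_json(truth_to_list(study$truth),
                         file.path(dir, "ground_truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(dir)
}

truth_to_list <- function(truth) {
  kin <- truth$kinetics
  list(
    water = unclass(truth$water),
    kinetics = list(p_n = kin$p_n, f = kin$f, p_s1 = kin$p_s1,
                    d_s1 = kin$d_s1, p_s2 = kin$p_s2, d_s2 = kin$d_s2,
                    k = kin$k, c = kin$c, Delta = kin$Delta),
    telomere = unclass(truth$telomere),
    A = truth$A
  )
}

truth_from_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  kin <- x$kinetics
  list(
    water = do.call(body_water_params, x$water),
    kinetics = explicit_params(p_n = kin$p_n, f = kin$f, p_s1 = kin$p_s1,
                               d_s1 = kin$d_s1, p_s2 = kin$p_s2,
                               d_s2 = kin$d_s2, k = kin$k, c = kin$c,
                               Delta = kin$Delta),
    telomere = do.call(telomere_params, x$telomere),
    A = x$A
  )
}

#' Run the full analysis pipeline on a study
#'
#' Reproduces the analysis order of a labelling study: body-water fits per
#' subject, homogeneity tests per subject and lineage with pooled
#' p-values, a clonal-expansion scan, explicit-model fits against all
#' available datasets, and stochastic precursor-lifespan simulations for
#' the fitted slow subpopulation.  Each stage writes a tidy CSV into
#' `outdir`, and a JSON manifest records the seed, configuration hash,
#' package version and per-stage status.  Reruns with the same inputs and
#' seed reproduce the result tables byte for byte.
#'
#' @param study A `tscm_study`.
#' @param outdir Output directory.
#' @param seed Master seed.
#' @param config A [fit_config()] used as the base configuration.
#' @param k_values Values scanned in the clonal-expansion stage.
#' @param scan_lineage Lineage used for the scan stage.
#' @param n_lifespan_runs Gillespie runs per subject in the lifespan stage.
#' @param subjects Subjects to analyse (default: all with label data).
#' @return Invisibly, a list with the per-stage tables and the manifest.
#' @export
run_pipeline <- function(study, outdir, seed = 1,
                         config = fit_config(n_starts = 20, seed = seed),
                         k_values = c(0, 2, 5, 10),
                         scan_lineage = "CD8",
                         n_lifespan_runs = 200,
                         subjects = NULL) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  status <- list()
  tables <- list()
  stage <- function(name, expr) {
    res <- try(expr, silent = TRUE)
    ok <- !inherits(res, "try-error")
    status[[name]] <<- if (ok) "ok" else paste("failed:", as.character(res))
    if (!ok) {
      write_manifest(study, outdir, seed, config, status)
      abort(sprintf("pipeline stage '%s' failed: %s", name, as.character(res)))
    }
    res
  }
  if (is.null(subjects)) subjects <- unique(study$label$subject_id)

  tables$water <- stage("water", {
    wf <- fit_water(study$saliva, tau = study$design$tau %||% 49)
    readr::write_csv(wf, file.path(outdir, "water_fits.csv"), progress = FALSE)
    wf
  })

  tables$homogeneity <- stage("homogeneity", {
    combos <- tidyr::expand_grid(subject_id = subjects,
                                 lineage = unique(study$label$lineage))
    rows <- purrr::pmap(combos, function(subject_id, lineage) {
      fd <- study_subset(study, subject_id, lineage)
      cfg <- config
      cfg$datasets <- intersect(config$datasets, c("label", "telomere"))
      th <- test_homogeneity(fd, cfg)
      dplyr::bind_cols(tibble::tibble(subject_id = subject_id,
                                      lineage = lineage), th$test,
                       tibble::tibble(ssr_homogeneous = th$fit_reduced$ssr,
                                      ssr_heterogeneous = th$fit_full$ssr))
    })
    hom <- dplyr::bind_rows(rows)
    pooled <- hom |>
      dplyr::group_by(.data$lineage) |>
      dplyr::summarise(tidy_pool = list(pool_pvalues(.data$p_value)),
                       .groups = "drop") |>
      tidyr::unnest("tidy_pool")
    readr::write_csv(hom, file.path(outdir, "homogeneity.csv"), progress = FALSE)
    readr::write_csv(pooled, file.path(outdir, "homogeneity_pooled.csv"),
                     progress = FALSE)
    list(tests = hom, pooled = pooled)
  })

  tables$kscan <- stage("kscan", {
    fd <- study_subset(study, subjects[1], scan_lineage)
    cfg <- config
    cfg$datasets <- intersect(config$datasets, c("label", "telomere"))
    ks <- k_scan(fd, cfg, k_values = k_values)
    out <- dplyr::select(ks, -"fit")
    readr::write_csv(out, file.path(outdir, "kscan.csv"), progress = FALSE)
    out
  })

  tables$explicit <- stage("explicit", {
    rows <- purrr::map(subjects, function(s) {
      has_yfv <- !is.null(study$yfv)
      fd <- study_subset(study, s, scan_lineage, include_yfv = has_yfv)
      cfg <- config
      cfg$variant <- "explicit"
      cfg$datasets <- intersect(
        c("label", "telomere", if (has_yfv) "yfv"),
        c(config$datasets, if (has_yfv) "yfv")
      )
      fit <- fit_model(fd, cfg)
      dplyr::bind_cols(tibble::tibble(subject_id = s, ssr = fit$ssr),
                       tibble::as_tibble(as.list(fit$estimates)), fit$derived)
    })
    ex <- dplyr::bind_rows(rows)
    med <- dplyr::summarise(ex, dplyr::across(dplyr::where(is.numeric), median))
    med$subject_id <- "MEDIAN"
    ex_out <- dplyr::bind_rows(ex, med)
    readr::write_csv(ex_out, file.path(outdir, "explicit_fits.csv"),
                     progress = FALSE)
    ex_out
  })

  tables$lifespans <- stage("lifespans", {
    ex <- dplyr::filter(tables$explicit, .data$subject_id != "MEDIAN")
    Delta <- if (!is.null(study$truth)) study$truth$kinetics$Delta else 1e-5
    rows <- purrr::pmap(
      list(ex$subject_id, ex$p_s2, ex$net_loss2, ex$f), function(s, p2, nl2, f) {
        kin <- explicit_params(p_n = 5e-4, f = f, p_s1 = 0.02, d_s1 = 0.05,
                               p_s2 = p2, d_s2 = p2 + nl2,
                               k = config$k, Delta = Delta)
        res <- precursor_lifespan_distribution(
          kin, mode = "long_lived", n_runs = n_lifespan_runs,
          seed = seed + match(s, ex$subject_id)
        )
        dplyr::bind_cols(tibble::tibble(subject_id = s, n0 = res$n0),
                         res$summary)
      })
    ls <- dplyr::bind_rows(rows)
    readr::write_csv(ls, file.path(outdir, "lifespans.csv"), progress = FALSE)
    ls
  })

  manifest <- write_manifest(study, outdir, seed, config, status)
  invisible(c(tables, list(manifest = manifest)))
}

write_manifest <- function(study, outdir, seed, config, status) {
  manifest <- list(
    package = "tscmdyn",
    version = as.character(utils::packageVersion("tscmdyn")),
    seed = seed,
    config_hash = rlang::hash(list(config, seed)),
    input_hash = rlang::hash(list(study$saliva, study$label, study$telomere,
                                  study$yfv)),
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE),
    stages = status
  )
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  manifest
}
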