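# End-to-end orchestration: one config drives the nine-stage workflow and a
# report bundle (ranked lists, simulation tables, flags, audit trail).

#' Read a workflow configuration
#'
#' YAML or JSON file (by extension) holding: paths to solvent / solubility /
#' curve tables (`solvent_table`, `solubility_table`, `curves`), the API and
#' impurity names (`api`, `impurities`), `crystallization` settings
#' (`candidates`: list of solvent/hot_loading/cold_solubility entries;
#' `min_ratio`, `max_ratio`), `wash` filter settings (any
#' [wash_filter_config()] field plus `cryst_solvent`), `experiments` (each a
#' [paracetamol_experiment()]-shaped list), `model` (`"A"`, `"B"` or
#' `"both"`), `output_dir`, `seed`, `stop_after_stage`.
#'
#' @param path Config file path.
#' @return The config as a named list (class `workflow_config`).
#' @export
read_workflow_config <- function(path) {
  if (!file.exists(path)) stop_fmt("config file not found: %s", path)
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  structure(cfg, class = c("workflow_config", "list"))
}

workflow_stages <- c("crystallization_ranking", "wash_ranking",
                     "curve_screening", "model_a", "model_b")

#' Run the solvent-selection and isolation workflow
#'
#' Executes, in order: crystallization-solvent ranking, wash-solvent
#' filtering and Pareto ranking, binary-curve screening (interior-maximum
#' detection), the displacement-washing simulator (model A) and optionally
#' the dispersion simulator (model B). Every applied filter and its
#' threshold is recorded in the audit log; a stage error halts the run
#' naming the stage and the offending record.
#'
#' @param config A `workflow_config` (list) or a path readable by
#'   [read_workflow_config()]. When `NULL`, runs the bundled paracetamol
#'   case study.
#' @param stop_after_stage Optional stage name (one of
#'   `"crystallization_ranking"`, `"wash_ranking"`, `"curve_screening"`,
#'   `"model_a"`, `"model_b"`) for partial execution.
#' @return `workflow_report`: list of per-stage results plus `audit` (a
#'   character vector of log lines).
#' @export
run_workflow <- function(config = NULL, stop_after_stage = NULL) {
  if (is.character(config)) config <- read_workflow_config(config)
  audit <- character(0)
  log <- function(...) audit <<- c(audit, sprintf(...))
  done <- function(stage) !is.null(stop_after_stage) &&
    stage == stop_after_stage
  stage_try <- function(stage, expr) {
    tryCatch(expr, error = function(e)
      stop_fmt("workflow halted at stage '%s': %s", stage, conditionMessage(e)))
  }
  use_bundled <- is.null(config)
  out <- list()

  # stages 1-4: crystallization ranking
  out$crystallization_ranking <- stage_try("crystallization_ranking", {
    if (use_bundled || is.null(config$crystallization$candidates)) {
      tab <- paracetamol_cryst_table()
      cands <- lapply(seq_len(nrow(tab)), function(i)
        cryst_candidate(tab$solvent[i],
                        hot_loading = tab$cold_solubility_g_per_g[i] +
                          tab$return_g[i] / 100,
                        cold_solubility = tab$cold_solubility_g_per_g[i],
                        solvent_mass = 100))
    } else {
      cands <- lapply(config$crystallization$candidates, function(cc)
        cryst_candidate(cc$solvent, cc$hot_loading, cc$cold_solubility,
                        cc$solvent_mass %||% 100))
    }
    mn <- config$crystallization$min_ratio %||% 3.5
    mx <- config$crystallization$max_ratio %||% 10
    log("stage crystallization_ranking: %d candidates, suspension limits %.2g-%.2g g/g",
        length(cands), mn, mx)
    rank_crystallization_solvents(cands, min_ratio = mn, max_ratio = mx)
  })
  if (done("crystallization_ranking"))
    return(structure(c(out, list(audit = audit)), class = "workflow_report"))

  # stages 5: wash filtering + Pareto ranking
  out$wash_ranking <- stage_try("wash_ranking", {
    solv_tab <- if (!is.null(config$solvent_table))
      read_solvent_table(config$solvent_table) else paracetamol_solvents()
    sol_tab <- if (!is.null(config$solubility_table))
      read_solubility_table(config$solubility_table)
    else paracetamol_solubilities()
    api <- config$api %||% "paracetamol"
    imps <- unlist(config$impurities) %||% c("acetanilide", "metacetamol")
    cryst_name <- config$wash$cryst_solvent %||% "2-propanol"
    cryst <- get_solvent(solv_tab, cryst_name)
    cryst_api_sol <- lookup_solubility(sol_tab, api, cryst_name)
    wcfg_fields <- intersect(names(config$wash %||% list()),
                             names(formals(wash_filter_config)))
    wcfg <- do.call(wash_filter_config, (config$wash %||% list())[wcfg_fields])
    pool <- setdiff(names(solv_tab$solvents), canon_name(cryst_name))
    cands <- lapply(pool, function(nm) {
      s <- solv_tab$solvents[[nm]]
      a <- lookup_solubility(sol_tab, api, nm, default = NA_real_)
      if (is.na(a)) return(NULL)
      isol <- vapply(imps, function(i)
        lookup_solubility(sol_tab, i, nm, default = NA_real_), numeric(1))
      if (any(is.na(isol))) return(NULL)
      wash_candidate(s, a, isol)
    })
    skipped <- pool[vapply(cands, is.null, logical(1))]
    if (length(skipped))
      log("stage wash_ranking: skipped (no solubility data): %s",
          paste(skipped, collapse = ", "))
    cands <- Filter(Negate(is.null), cands)
    log("stage wash_ranking: %d candidates vs crystallization solvent %s; filters: bp/mp margin %g C of %g C, density ratio <= %g, mp < %g, bp %g-%g, viscosity < %g, Vp < %g, ICH >= %g, GSK > %g",
        length(cands), cryst_name, wcfg$bp_mp_exclusion_margin,
        wcfg$wash_temperature, wcfg$density_ratio_max, wcfg$mp_max,
        wcfg$bp_range[1], wcfg$bp_range[2], wcfg$viscosity_max,
        wcfg$vapor_pressure_max, wcfg$ich_min_class, wcfg$gsk_min_score)
    cands <- apply_hard_filters(cands, cryst, cryst_api_sol, wcfg)
    cands <- apply_threshold_filters(cands, wcfg)
    rk <- pareto_rank(cands)
    rk$advisory <- drying_friendliness(cands, cryst)
    rk
  })
  if (done("wash_ranking"))
    return(structure(c(out, list(audit = audit)), class = "workflow_report"))

  # stage 6: binary-curve screening
  out$curve_screening <- stage_try("curve_screening", {
    curves <- if (!is.null(config$curves)) read_binary_curves(config$curves)
    else {
      exps <- config$experiments %||% c("Exp1", "Exp2", "Exp3")
      cl <- list()
      for (e in exps) {
        p <- if (is.list(e)) e else paracetamol_experiment(e)
        cs <- paracetamol_curves(p)
        names(cs) <- paste(names(cs), p$cryst_solvent, p$wash_solvent,
                           sep = "|")
        cl <- c(cl, cs)
      }
      cl
    }
    scr <- do.call(rbind, lapply(names(curves), function(k) {
      mx <- detect_maximum(curves[[k]])
      data.frame(curve = k, has_interior_maximum = mx$has_interior_maximum,
                 location = mx$location, stringsAsFactors = FALSE)
    }))
    log("stage curve_screening: %d curves, %d with dissolution-risk maxima",
        nrow(scr), sum(scr$has_interior_maximum))
    scr
  })
  if (done("curve_screening"))
    return(structure(c(out, list(audit = audit)), class = "workflow_report"))

  model <- toupper(config$model %||% "both")
  exps <- config$experiments %||% c("Exp1", "Exp2", "Exp3")

  if (model %in% c("A", "BOTH")) {
    out$model_a <- stage_try("model_a", {
      res <- lapply(exps, function(e) run_paracetamol_model_a(e))
      names(res) <- vapply(exps, function(e)
        if (is.list(e)) e$name else e, character(1))
      for (nm in names(res))
        log("stage model_a [%s]: final removal %s",
            nm, paste(sprintf("%.1f%%",
                              unlist(res[[nm]]$checkpoints[
                                nrow(res[[nm]]$checkpoints),
                                grep("^removed_",
                                     names(res[[nm]]$checkpoints))])),
                      collapse = ", "))
      res
    })
  }
  if (done("model_a"))
    return(structure(c(out, list(audit = audit)), class = "workflow_report"))

  if (model %in% c("B", "BOTH")) {
    out$model_b <- stage_try("model_b", {
      res <- lapply(exps, function(e) run_paracetamol_model_b(e))
      names(res) <- vapply(exps, function(e)
        if (is.list(e)) e$name else e, character(1))
      log("stage model_b: %d experiments simulated", length(res))
      res
    })
  }
  structure(c(out, list(audit = audit)), class = "workflow_report")
}

#' Write a workflow report bundle
#'
#' Emits one CSV (or markdown) table per stage plus the audit/flags log,
#' with a provenance header (software version and a content hash of the
#' result object).
#'
#' @param report A `workflow_report` from [run_workflow()].
#' @param dir Output directory (created if needed).
#' @param format `"csv"` or `"markdown"`.
#' @return Character vector of files written, invisibly.
#' @export
write_report <- function(report, dir, format = c("csv", "markdown")) {
  format <- match.arg(format)
  stopifnot(inherits(report, "workflow_report"))
  if (!dir.exists(dir))
    if (!dir.create(dir, recursive = TRUE, showWarnings = FALSE))
      stop_fmt("cannot create output directory '%s'", dir)
  ver <- as.character(utils::packageVersion("solvselect"))
  hash <- sum(utf8ToInt(paste(utils::capture.output(utils::str(report)),
                              collapse = "")))
  header <- sprintf("# solvselect %s | config hash %d", ver, hash)
  files <- character(0)
  emit <- function(name, df) {
    if (is.null(df) || !nrow(df)) {
      df <- data.frame(note = "no candidates passed filters")
    }
    if (format == "csv") {
      f <- file.path(dir, paste0(name, ".csv"))
      con <- file(f, "w")
      writeLines(header, con)
      utils::write.csv(df, con, row.names = FALSE)
      close(con)
    } else {
      f <- file.path(dir, paste0(name, ".md"))
      cols <- names(df)
      fmt1 <- function(v) vapply(v, function(x)
        if (is.numeric(x)) format(x, digits = 5) else as.character(x),
        character(1))
      lines <- c(header, "", paste0("| ", paste(cols, collapse = " | "), " |"),
                 paste0("|", paste(rep("---", length(cols)), collapse = "|"),
                        "|"),
                 apply(df, 1, function(r)
                   paste0("| ", paste(fmt1(r), collapse = " | "), " |")))
      writeLines(lines, f)
    }
    files <<- c(files, f)
  }
  if (!is.null(report$crystallization_ranking)) {
    emit("crystallization_ranking", report$crystallization_ranking$ranking)
    emit("crystallization_excluded", report$crystallization_ranking$excluded)
  }
  if (!is.null(report$wash_ranking)) {
    emit("wash_ranking", report$wash_ranking$ranking)
    emit("wash_flagged", report$wash_ranking$flagged)
  }
  if (!is.null(report$curve_screening))
    emit("curve_screening", report$curve_screening)
  for (m in c("model_a", "model_b")) {
    if (is.null(report[[m]])) next
    for (nm in names(report[[m]]))
      emit(paste0(m, "_", nm), report[[m]][[nm]]$checkpoints)
  }
  flag_lines <- c(header, "", "flags log:")
  for (m in c("model_a", "model_b")) {
    if (is.null(report[[m]])) next
    for (nm in names(report[[m]])) {
      fl <- report[[m]][[nm]]$flags
      if (isTRUE(fl$api_dissolution$fired))
        flag_lines <- c(flag_lines,
                        sprintf("%s %s: API dissolution risk (wash %s)",
                                m, nm, fl$api_dissolution$wash))
      for (im in names(fl$impurity_precipitation))
        if (isTRUE(fl$impurity_precipitation[[im]]$fired))
          flag_lines <- c(flag_lines,
                          sprintf("%s %s: %s precipitation risk (wash %s)",
                                  m, nm, im,
                                  fl$impurity_precipitation[[im]]$wash))
    }
  }
  logf <- file.path(dir, if (format == "markdown") "run_log.md" else
    "run_log.txt")
  writeLines(c(flag_lines, "", "audit:", report$audit), logf)
  files <- c(files, logf)
  invisible(files)
}

#' @export
print.workflow_report <- function(x, ...) {
  cat("<workflow_report> stages:",
      paste(intersect(workflow_stages, names(x)), collapse = ", "), "\n")
  cat(sprintf("  audit: %d log lines\n", length(x$audit)))
  invisible(x)
}
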