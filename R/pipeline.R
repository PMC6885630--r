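# YAML run configuration and end-to-end orchestration
# (simulate -> parse -> profile) with a reproducibility manifest. Structured
# log lines go to stderr; data go to files only.

# `n_reads` rather than bare `n`: YAML 1.1 parses an unquoted `n` key as a
# boolean, so the schema avoids it (a bare `n` is still accepted from lists).
.CONFIG_KEYS <- c("design", "n_reads", "n", "seed", "outdir", "template",
                  "tso", "preset", "params", "parser", "tail_mean", "adapter",
                  "baseline_comp")
.TEMPLATE_KEYS <- c("design", "first_bases", "end_chem", "name")
.TSO_KEYS <- c("ribo3", "body_dna", "biotin5", "name")
.PARAMS_KEYS <- c("eta", "sigma", "kappa_ts", "w_gc", "w_at", "kappa_blunt",
                  "cap_c_prob", "dntp_conc", "alpha", "max_switches",
                  "max_nta", "delay_steps", "seq_error_rate")
.PARSER_KEYS <- c("anchor21", "adapter", "max_anchor_mismatches",
                  "adapter_match_len")

.reject_unknown <- function(x, allowed, where) {
  unknown <- setdiff(names(x), allowed)
  if (length(unknown))
    stop("configuration error in ", where, ": unknown key(s): ",
         paste(unknown, collapse = ", "))
}

.as_named_numeric <- function(x) {
  if (is.list(x)) unlist(x) else x
}

#' Validate and resolve a run configuration
#'
#' Reads a YAML run config (or takes an equivalent named list), validates it
#' against the schema -- unknown keys are rejected, a seed is mandatory --
#' and resolves defaults into a fully-specified `run_config`. The resolved
#' values are echoed to stderr.
#'
#' Schema (top-level keys): `design` (NTA/JUNCTION/COMPOSITION), `n`, `seed`
#' (required), `outdir`, `template` (`design`, `first_bases`, `end_chem`),
#' `tso` (`ribo3`, optional `body_dna`, `biotin5`; omit for no-TSO runs),
#' `preset` (capped/oh/p) and/or `params` (overrides of [sim_params()]
#' fields), `parser` (overrides of [parser_config()] fields), `tail_mean`,
#' `adapter`, `baseline_comp`.
#'
#' @param config Path to a YAML file, or a named list.
#' @return Object of class `run_config`.
#' @export
validate_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("configuration file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stop("configuration error: config must be a mapping")
  .reject_unknown(config, .CONFIG_KEYS, "config")

  if (is.null(config$design))
    stop("configuration error: missing key `design`")
  design <- toupper(config$design)
  if (!design %in% c("NTA", "JUNCTION", "COMPOSITION"))
    stop("configuration error in `design`: must be NTA, JUNCTION or COMPOSITION")
  if (is.null(config$seed))
    stop("configuration error: `seed` is mandatory for simulation runs")
  seed <- as.integer(config$seed)
  n <- as.integer(config$n_reads %||% config$n %||% 1000L)
  if (is.na(n) || n <= 0) stop("configuration error in `n_reads`: must be > 0")

  tpl <- config$template %||% list()
  .reject_unknown(tpl, .TEMPLATE_KEYS, "template")
  template <- build_template(
    design = toupper(tpl$design %||% "FOUR_RN"),
    first_bases = toupper(tpl$first_bases %||%
                            if (toupper(tpl$design %||% "FOUR_RN") == "SINGLE_N") "N"
                            else "NNNN"),
    end_chem = toupper(tpl$end_chem %||% "M7G_CAP"),
    name = tpl$name)

  tso_obj <- NULL
  if (!is.null(config$tso)) {
    .reject_unknown(config$tso, .TSO_KEYS, "tso")
    if (is.null(config$tso$ribo3))
      stop("configuration error in `tso`: missing key `ribo3`")
    tso_obj <- tso(ribo3 = config$tso$ribo3,
                   body_dna = config$tso$body_dna %||% DEFAULT_TSO_BODY,
                   biotin5 = isTRUE(config$tso$biotin5),
                   name = config$tso$name)
  }

  overrides <- config$params %||% list()
  .reject_unknown(overrides, .PARAMS_KEYS, "params")
  if (!is.null(overrides$eta)) {
    eta <- overrides$eta
    overrides$eta <- if (is.list(eta) && is.list(eta[[1]]))
      do.call(rbind, lapply(eta, .as_named_numeric))
    else .as_named_numeric(eta)
  }
  if (!is.null(overrides$dntp_conc))
    overrides$dntp_conc <- .as_named_numeric(overrides$dntp_conc)
  params <- tryCatch({
    if (!is.null(config$preset)) do.call(sim_preset, c(list(name = config$preset), overrides))
    else do.call(sim_params, overrides)
  }, error = function(e) stop("configuration error in `params`: ",
                              conditionMessage(e), call. = FALSE))

  pcfg <- config$parser %||% list()
  .reject_unknown(pcfg, .PARSER_KEYS, "parser")
  parser <- parser_config(
    design = design,
    anchor21 = pcfg$anchor21 %||% ANCHOR21_DEFAULT,
    adapter = pcfg$adapter %||% config$adapter %||% DEFAULT_APP_ADAPTER,
    ctso = if (design == "JUNCTION") {
      if (is.null(tso_obj))
        stop("configuration error: JUNCTION design requires a `tso` block")
      cdna_of_tso(tso_obj)
    },
    max_anchor_mismatches = pcfg$max_anchor_mismatches %||% 2L,
    adapter_match_len = pcfg$adapter_match_len %||% 15L,
    n_var = length(template$variable_positions))

  out <- structure(
    list(design = design, n = n, seed = seed,
         outdir = config$outdir %||% "switchsim_run",
         template = template, tso = tso_obj, params = params,
         parser = parser,
         tail_mean = as.numeric(config$tail_mean %||% 12),
         adapter = config$adapter %||% DEFAULT_APP_ADAPTER,
         baseline_comp = if (!is.null(config$baseline_comp))
           .as_named_numeric(config$baseline_comp)),
    class = "run_config")
  .log("resolved config: design=%s n=%d seed=%d end_chem=%s tso=%s",
       design, n, seed, template$end_chem,
       if (is.null(tso_obj)) "none" else tso_obj$name)
  out
}

.log <- function(fmt, ...) {
  message(sprintf(paste0("[switchsim] ", fmt), ...))
}

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  path
}

#' Run the simulate -> parse -> profile pipeline
#'
#' Executes the stages in order, writes all artifacts under
#' `config$outdir`, and returns a JSON-serializable manifest (paths, md5
#' checksums, parameter echo, parser status counts). Identical
#' `(config, seed)` produce byte-identical FASTQ/TSV outputs.
#'
#' @param config A [validate_config()] result (or something coercible by it).
#' @param outdir Optional override of the configured output directory.
#' @return The manifest, invisibly; also written as `manifest.json`.
#' @export
run_pipeline <- function(config, outdir = NULL) {
  if (!inherits(config, "run_config")) config <- validate_config(config)
  outdir <- outdir %||% config$outdir
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

  .log("simulating %d %s reads (seed %d)", config$n, config$design, config$seed)
  lib <- simulate_library(config$design, config$n, config$template,
                          tso = config$tso, params = config$params,
                          seed = config$seed,
                          baseline_comp = config$baseline_comp,
                          tail_mean = config$tail_mean,
                          adapter = config$adapter)
  paths <- list(
    fastq = file.path(outdir, "reads.fastq"),
    truth = file.path(outdir, "truth.tsv"),
    parsed = file.path(outdir, "parsed.tsv"),
    parse_summary = file.path(outdir, "parse_summary.json"),
    manifest = file.path(outdir, "manifest.json"))
  write_fastq(lib$reads$read_id, lib$reads$seq, paths$fastq)
  .write_tsv(lib$truth, paths$truth)

  .log("parsing %d reads", config$n)
  parsed <- parse_reads(lib$reads$seq, config$parser, ids = lib$reads$read_id)
  .write_tsv(parsed, paths$parsed)
  summary <- parse_summary(parsed)
  jsonlite::write_json(summary, paths$parse_summary, auto_unbox = TRUE)

  ok <- parsed[parsed$status == "OK", , drop = FALSE]
  .log("profiling %d OK reads", nrow(ok))
  if (nrow(ok) > 0) {
    comp <- positional_composition(ok$n_bases)
    comp_df <- data.frame(position = rep(rownames(comp$counts), 4),
                          base = rep(colnames(comp$counts), each = nrow(comp$counts)),
                          count = as.vector(comp$counts),
                          fraction = as.vector(comp$fractions))
    paths$composition <- .write_tsv(comp_df, file.path(outdir, "composition.tsv"))
    if (config$design %in% c("NTA", "JUNCTION")) {
      prof_fun <- if (config$design == "NTA") nta_profile else junction_profile
      prof <- prof_fun(ok$payload, first_base = substr(ok$n_bases, 1, 1))
      prof_df <- do.call(rbind, lapply(names(prof$strata), function(st) {
        s <- prof$strata[[st]]
        rbind(data.frame(stratum = st, kind = "string",
                         category = names(s$string_freq),
                         fraction = as.numeric(s$string_freq), n = s$n),
              data.frame(stratum = st, kind = "length",
                         category = names(s$length_freq),
                         fraction = as.numeric(s$length_freq), n = s$n))
      }))
      paths$profile <- .write_tsv(prof_df, file.path(outdir, "profile.tsv"))
    }
  }

  files <- unlist(paths[names(paths) != "manifest"])
  manifest <- list(
    package = "switchsim",
    design = config$design,
    n = config$n,
    seed = config$seed,
    end_chem = config$template$end_chem,
    tso = if (!is.null(config$tso)) config$tso$name else "none",
    params = .params_echo(config$params),
    status_counts = summary,
    switch_fraction = mean(lib$truth$n_switches > 0),
    files = lapply(files, function(f)
      list(path = f, md5 = unname(tools::md5sum(f)))))
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  .log("manifest written to %s", paths$manifest)
  invisible(manifest)
}

.params_echo <- function(p) {
  list(eta = apply(p$eta, 1, as.list),
       sigma = p$sigma, kappa_ts = p$kappa_ts, w_gc = p$w_gc, w_at = p$w_at,
       kappa_blunt = p$kappa_blunt, cap_c_prob = p$cap_c_prob,
       dntp_conc = as.list(stats::setNames(p$dntp_conc, DNA_BASES)),
       alpha = p$alpha, max_switches = p$max_switches,
       max_nta = if (is.finite(p$max_nta)) p$max_nta else "Inf",
       delay_steps = p$delay_steps, seq_error_rate = p$seq_error_rate)
}
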