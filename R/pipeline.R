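#' Run the end-to-end analysis pipeline
#'
#' Executes the stages in dependency order — simulate (or load), prep
#' (QC filter + adjacent-normal collapsing), differential expression for
#' the two progression contrasts, monotone panel selection and progression
#' scores, seeding-focus calls and seeding DE panels — writing every stage
#' output as TSV under `out_dir` and returning a manifest with the full
#' parameter echo, the seed, and an md5 hash of every file produced.
#' Rerunning with an identical config and seed reproduces identical
#' hashes. No stage mutates its inputs.
#'
#' @param config named list (or path to a YAML file) with optional entries:
#'   `seed`, `out_dir`, `counts`/`annotation` (paths; when absent a
#'   synthetic dataset is generated), `sim` (list of [sim_config()]
#'   overrides), `lfc_thresh`, `fdr_thresh`, `fdr_panel`, `fdr_broad`,
#'   `k_list`.
#' @param out_dir output directory; overrides `config$out_dir`.
#' @param seed integer seed; overrides `config$seed`.
#' @return the manifest (list), invisibly written to
#'   `file.path(out_dir, "manifest.json")`.
#' @export
run_pipeline <- function(config = list(), out_dir = NULL, seed = NULL) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  seed <- as.integer(seed %||% config$seed %||% 1L)
  out_dir <- out_dir %||% config$out_dir %||% stop("no output directory given")
  if (!is.null(config$counts) && !file.exists(config$counts))
    stop("input file not found: ", config$counts)
  if (!is.null(config$annotation) && !file.exists(config$annotation))
    stop("input file not found: ", config$annotation)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  params <- list(seed = seed,
                 lfc_thresh = config$lfc_thresh %||% 2,
                 fdr_thresh = config$fdr_thresh %||% 0.05,
                 fdr_panel = config$fdr_panel %||% 0.01,
                 fdr_broad = config$fdr_broad %||% 0.05,
                 k_list = config$k_list %||% c(500, 100, 50))
  stages <- character()
  run_stage <- function(name, fun) {
    res <- tryCatch(fun(), error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)), call. = FALSE))
    stages <<- c(stages, name)
    res
  }

  dat <- run_stage("simulate", function() {
    if (!is.null(config$counts)) {
      list(expr = read_expression(config$counts, "counts"),
           annotation = read_table_tsv(config$annotation), truth = NULL)
    } else {
      sim_args <- config$sim %||% list()
      sim_args$seed <- seed
      sim <- gen_multifocal_counts(do.call(sim_config, sim_args))
      write_simulation(sim, file.path(out_dir, "simulated"))
      sim
    }
  })

  ann <- run_stage("prep", function() {
    a <- if ("qc_pass" %in% names(dat$annotation)) qc_filter(dat$annotation) else dat$annotation
    a <- collapse_an(a)
    write_table_tsv(a, file.path(out_dir, "annotation_prepped.tsv"))
    a
  })
  expr <- dat$expr[, ann$sample_id, drop = FALSE]

  de <- run_stage("de", function() {
    contrast <- function(g1, g2) {
      sel <- ann$tissue_type %in% c(g1, g2)
      nb_exact_test(expr[, ann$sample_id[sel], drop = FALSE],
                    factor(ann$tissue_type[sel], levels = c(g1, g2)))
    }
    de_an_can <- contrast("AN", "CAN")
    de_can_met <- contrast("CAN", "MET")
    write_table_tsv(de_an_can, file.path(out_dir, "de_an_can.tsv"))
    write_table_tsv(de_can_met, file.path(out_dir, "de_can_met.tsv"))
    list(an_can = de_an_can, can_met = de_can_met)
  })

  prog <- run_stage("progression", function() {
    panel <- select_monotone(de$an_can, de$can_met,
                             params$lfc_thresh, params$fdr_thresh)
    scores <- if (length(panel)) progression_score(expr, panel) else
      stats::setNames(numeric(0), character(0))
    write_table_tsv(data.frame(gene_id = panel$gene_ids, direction = panel$direction),
                    file.path(out_dir, "progression_panel.tsv"))
    write_table_tsv(data.frame(sample_id = names(scores), score = unname(scores)),
                    file.path(out_dir, "progression_scores.tsv"))
    list(panel = panel, scores = scores)
  })

  seeding <- run_stage("seeding", function() {
    lg <- to_log2(normalize_counts(expr))
    calls <- call_seeding_all(lg, ann, k_list = params$k_list)
    write_table_tsv(calls, file.path(out_dir, "seeding_calls.tsv"))
    resolved <- calls[calls$status == "resolved", , drop = FALSE]
    panels <- NULL
    if (nrow(resolved)) {
      seedsamp <- nonseed <- character()
      for (i in seq_len(nrow(resolved))) {
        p <- resolved$patient_id[i]
        cans <- ann[ann$patient_id == p & ann$tissue_type == "CAN", ]
        is_seed <- !is.na(cans$focus_label) & cans$focus_label == resolved$seeding_focus[i]
        seedsamp <- c(seedsamp, cans$sample_id[is_seed])
        nonseed <- c(nonseed, cans$sample_id[!is_seed])
      }
      panels <- seeding_de(expr, seedsamp, nonseed,
                           params$fdr_panel, params$fdr_broad)
      write_table_tsv(panels$de, file.path(out_dir, "seeding_de.tsv"))
      write_table_tsv(data.frame(gene_id = panels$strict$gene_ids,
                                 direction = panels$strict$direction),
                      file.path(out_dir, "seeding_panel_strict.tsv"))
    }
    list(calls = calls, panels = panels)
  })

  files <- list.files(out_dir, recursive = TRUE, full.names = TRUE)
  files <- setdiff(files, file.path(out_dir, "manifest.json"))
  hashes <- tools::md5sum(sort(files))
  names(hashes) <- sub(paste0("^", out_dir, "/?"), "", names(hashes))
  manifest <- list(stages = stages, parameters = params,
                   n_genes = nrow(expr), n_samples = ncol(expr),
                   panel_size = length(prog$panel),
                   n_resolved = sum(seeding$calls$status == "resolved"),
                   hashes = as.list(hashes))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
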