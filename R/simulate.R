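#' Simulation configuration for multifocal count data
#'
#' Describes a synthetic discovery cohort: per-patient sample design over the
#' five tissue types, negative-binomial noise, a set of planted
#' progression genes whose mean shifts monotonically along the
#' adjacent-normal -> primary-tumour -> metastasis axis, and a per-patient
#' "seeding" primary focus that shares a transcriptional shift with that
#' patient's metastasis.
#'
#' The default `tissue_design` reproduces the multifocal discovery layout of
#' ten radical-prostatectomy patients with 10 distant-normal, 13
#' proximal-normal, 23 primary-focus, 9 metastasis and 2 benign-lymph-node
#' samples in total, with between one and four primary foci per patient.
#'
#' @param n_patients number of patients (rows of `tissue_design`).
#' @param tissue_design data.frame with integer columns DAN, PAN, CAN, MET,
#'   LYMPH, one row per patient; NULL selects the default design (truncated
#'   or recycled to `n_patients` rows).
#' @param n_genes total number of genes.
#' @param n_monotone_genes number of planted progression genes.
#' @param monotone_lfc log2 fold change applied per transition (AN to CAN and
#'   again CAN to MET); negative means downregulation.
#' @param n_seeding_genes number of genes shared between the seeding focus
#'   and the metastasis.
#' @param seeding_lfc log2 shift of the seeding genes in the seeding focus
#'   and MET samples.
#' @param nb_dispersion negative-binomial dispersion alpha in the
#'   variance = mu + alpha * mu^2 parameterisation; must be > 0.
#' @param baseline_mean expected baseline count per gene at the average
#'   library size.
#' @param library_size_range length-2 range of per-sample library-size
#'   factors, drawn log-uniformly; factors multiply every gene mean.
#' @param seed integer seed.
#' @return a list of class `"sim_config"`.
#' @export
sim_config <- function(n_patients = 10,
                       tissue_design = NULL,
                       n_genes = 2000,
                       n_monotone_genes = 50,
                       monotone_lfc = -3,
                       n_seeding_genes = 50,
                       seeding_lfc = 3,
                       nb_dispersion = 0.1,
                       baseline_mean = 100,
                       library_size_range = c(0.5, 2),
                       seed = 1L) {
  if (is.null(tissue_design)) {
    # per-patient sample counts of the default ten-patient multifocal design
    tissue_design <- data.frame(
      DAN   = c(1, 1, 1, 1, 1, 1, 1, 0, 1, 2),
      PAN   = c(1, 1, 1, 2, 1, 1, 1, 0, 1, 4),
      CAN   = c(2, 1, 2, 1, 3, 1, 3, 2, 4, 4),
      MET   = c(1, 1, 1, 3, 1, 1, 1, 0, 0, 0),
      LYMPH = c(0, 1, 0, 1, 0, 0, 0, 0, 0, 0))
    tissue_design <- tissue_design[rep_len(seq_len(10), n_patients), , drop = FALSE]
    rownames(tissue_design) <- NULL
  }
  cfg <- list(n_patients = n_patients, tissue_design = tissue_design,
              n_genes = n_genes, n_monotone_genes = n_monotone_genes,
              monotone_lfc = monotone_lfc, n_seeding_genes = n_seeding_genes,
              seeding_lfc = seeding_lfc, nb_dispersion = nb_dispersion,
              baseline_mean = baseline_mean,
              library_size_range = library_size_range, seed = as.integer(seed))
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  if (cfg$n_patients < 1 || cfg$n_genes < 1)
    stop("invalid config: need at least one patient and one gene")
  if (nrow(cfg$tissue_design) != cfg$n_patients)
    stop("invalid config: tissue_design must have one row per patient")
  if (any(as.matrix(cfg$tissue_design) < 0))
    stop("invalid config: negative sample counts")
  if (cfg$n_monotone_genes + cfg$n_seeding_genes > cfg$n_genes)
    stop("invalid config: planted gene sets exceed n_genes")
  if (cfg$nb_dispersion <= 0) stop("invalid config: nb_dispersion must be > 0")
  if (length(cfg$library_size_range) != 2 || any(cfg$library_size_range <= 0))
    stop("invalid config: library_size_range must be two positive values")
  invisible(cfg)
}

# run expr with the RNG seeded, restoring the caller's RNG state afterwards
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has_old) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' Generate a multifocal negative-binomial count dataset
#'
#' Draws counts gene-by-sample from NB(mu, alpha) with
#' `mu = baseline_g * tissue multiplier * library factor`. Planted
#' progression genes get their mean multiplied by `2^monotone_lfc` in
#' primary-tumour (CAN) samples relative to adjacent normal, and by
#' `2^(2*monotone_lfc)` in metastases. Within each patient that has at least
#' one primary focus, one focus is designated the seeding focus; the seeding
#' genes are shifted by `2^seeding_lfc` in that focus and in the patient's
#' MET samples only. Identical seeds give identical output.
#'
#' @param config a [sim_config()].
#' @return list with `expr` (counts [expression_matrix()]), `annotation`
#'   (sample annotation data.frame with `sample_id`, `patient_id`,
#'   `tissue_type`, `focus_label`, `qc_pass`), `truth` (list:
#'   `monotone_gene_ids`, `seeding_gene_ids`, `seeding_focus_per_patient`,
#'   `library_factors`, `baseline_means`).
#' @export
gen_multifocal_counts <- function(config) {
  validate_sim_config(config)
  with_seed(config$seed, {
    G <- config$n_genes
    gene_ids <- sprintf("g%04d", seq_len(G))
    mono_ids <- if (config$n_monotone_genes) gene_ids[seq_len(config$n_monotone_genes)] else character()
    seed_ids <- if (config$n_seeding_genes)
      gene_ids[config$n_monotone_genes + seq_len(config$n_seeding_genes)] else character()

    # gene baseline abundances: lognormal spread around the configured mean,
    # kept moderate so planted fold changes stay estimable at low counts
    base_mu <- config$baseline_mean * exp(stats::rnorm(G, 0, 0.5) - 0.125)
    names(base_mu) <- gene_ids

    des <- config$tissue_design
    ann <- do.call(rbind, lapply(seq_len(config$n_patients), function(p) {
      rows <- lapply(c("DAN", "PAN", "CAN", "MET", "LYMPH"), function(tt) {
        k <- des[[tt]][p]
        if (!k) return(NULL)
        data.frame(sample_id = sprintf("PT%d_%s%d", p, tt, seq_len(k)),
                   patient_id = sprintf("PT%d", p), tissue_type = tt,
                   focus_label = if (tt == "CAN") sprintf("CAN%d", seq_len(k)) else NA_character_,
                   qc_pass = TRUE, stringsAsFactors = FALSE)
      })
      do.call(rbind, rows)
    }))
    rownames(ann) <- NULL
    S <- nrow(ann)

    # one seeding focus per patient with >= 1 primary focus, drawn uniformly
    seeding_focus <- list()
    for (p in unique(ann$patient_id)) {
      foci <- ann$focus_label[ann$patient_id == p & ann$tissue_type == "CAN"]
      if (length(foci))
        seeding_focus[[p]] <- foci[sample.int(length(foci), 1)]
    }

    lib <- exp(stats::runif(S, log(config$library_size_range[1]),
                            log(config$library_size_range[2])))
    names(lib) <- ann$sample_id

    mu <- matrix(base_mu, nrow = G, ncol = S,
                 dimnames = list(gene_ids, ann$sample_id))
    tt <- ann$tissue_type
    if (length(mono_ids)) {
      mu[mono_ids, tt == "CAN"] <- mu[mono_ids, tt == "CAN"] * 2^config$monotone_lfc
      mu[mono_ids, tt == "MET"] <- mu[mono_ids, tt == "MET"] * 2^(2 * config$monotone_lfc)
    }
    if (length(seed_ids)) {
      for (p in names(seeding_focus)) {
        sel <- (ann$patient_id == p) &
          ((ann$tissue_type == "MET") |
             (ann$tissue_type == "CAN" & !is.na(ann$focus_label) &
                ann$focus_label == seeding_focus[[p]]))
        if (any(sel))
          mu[seed_ids, sel] <- mu[seed_ids, sel] * 2^config$seeding_lfc
      }
    }
    mu <- sweep(mu, 2, lib, `*`)

    counts <- matrix(stats::rnbinom(G * S, mu = mu, size = 1 / config$nb_dispersion),
                     nrow = G, dimnames = dimnames(mu))

    list(expr = expression_matrix(counts, "counts"),
         annotation = ann,
         truth = list(monotone_gene_ids = mono_ids,
                      seeding_gene_ids = seed_ids,
                      seeding_focus_per_patient = unlist(seeding_focus),
                      library_factors = lib,
                      baseline_means = base_mu))
  })
}

#' Generate a survival cohort with expression-driven hazards
#'
#' One sample per patient. Panel-gene expression is lognormal; event times
#' are exponential with hazard `lambda0 * exp(sum(beta * x))` where `x` is
#' the centred log2 expression, and censoring times are independent
#' exponential with rate tuned so the expected censored fraction equals
#' `censoring_rate`. Clinicopathological covariates (pre-operative PSA,
#' Gleason group > 7, stage pT3, positive margin) are generated with a
#' configurable tie to the linear predictor.
#'
#' @param n_patients cohort size, at least 20.
#' @param panel a [gene_panel()] naming the signature genes.
#' @param beta named per-gene log-hazard coefficients (per unit centred log2
#'   expression); genes absent from `beta` get 0.
#' @param censoring_rate expected fraction censored, in [0, 1).
#' @param seed integer seed.
#' @param n_noise_genes extra unassociated genes appended to the matrix.
#' @param baseline_hazard exponential baseline rate per day.
#' @param covariate_assoc strength of the clinicopathological covariates'
#'   tie to the linear predictor (0 = independent).
#' @return list with `expr` (FPKM-like [expression_matrix()]), `clinical`
#'   (data.frame: `patient_id`, `time`, `event`, `psa`, `gleason_gt7`,
#'   `stage_pt3`, `margin_pos`, `nodal_pos`), and `truth` (list: `true_beta`,
#'   `linear_predictor`).
#' @export
gen_survival_cohort <- function(n_patients, panel, beta,
                                censoring_rate = 0.5, seed = 1L,
                                n_noise_genes = 0,
                                baseline_hazard = 1 / 1500,
                                covariate_assoc = 0) {
  if (n_patients < 20) stop("n_patients must be at least 20")
  if (censoring_rate < 0 || censoring_rate >= 1)
    stop("censoring_rate must be in [0, 1); an all-censored cohort is not allowed")
  genes <- panel$gene_ids
  if (!length(genes)) stop("empty gene panel")
  b <- stats::setNames(rep(0, length(genes)), genes)
  b[intersect(names(beta), genes)] <- beta[intersect(names(beta), genes)]

  with_seed(seed, {
    ids <- sprintf("P%04d", seq_len(n_patients))
    all_genes <- c(genes, if (n_noise_genes) sprintf("noise%04d", seq_len(n_noise_genes)))
    # lognormal FPKM-like expression, roughly centred on 16 = 2^4
    expr <- matrix(2^stats::rnorm(length(all_genes) * n_patients, mean = 4, sd = 1),
                   nrow = length(all_genes), dimnames = list(all_genes, ids))
    x <- log2(expr[genes, , drop = FALSE])
    xc <- x - rowMeans(x)
    eta <- as.numeric(crossprod(xc, b))

    haz <- baseline_hazard * exp(eta)
    t_event <- stats::rexp(n_patients, rate = haz)
    if (censoring_rate == 0) {
      time <- t_event; event <- rep(TRUE, n_patients)
    } else {
      # censoring rate lc solves E[ lc / (lc + haz) ] = censoring_rate
      f <- function(lc) mean(lc / (lc + haz)) - censoring_rate
      lc <- stats::uniroot(f, lower = 1e-12, upper = 1e6 * max(haz))$root
      t_cens <- stats::rexp(n_patients, rate = lc)
      time <- pmin(t_event, t_cens)
      event <- t_event <= t_cens
    }
    time <- pmax(time, 1e-3)  # strictly positive follow-up
    if (!any(event)) stop("generated cohort has zero events; lower censoring_rate")

    z <- covariate_assoc * scale(eta)[, 1]
    if (all(!is.finite(z))) z <- rep(0, n_patients)
    clinical <- data.frame(
      patient_id = ids, time = time, event = event,
      psa = exp(stats::rnorm(n_patients, mean = log(10) + 0.3 * z, sd = 0.6)),
      gleason_gt7 = stats::runif(n_patients) < stats::plogis(-0.5 + z),
      stage_pt3 = stats::runif(n_patients) < stats::plogis(0 + z),
      margin_pos = stats::runif(n_patients) < stats::plogis(-0.7 + 0.5 * z),
      nodal_pos = stats::runif(n_patients) < stats::plogis(-2 + 0.5 * z),
      stringsAsFactors = FALSE)

    list(expr = expression_matrix(expr, "fpkm"),
         clinical = clinical,
         truth = list(true_beta = b, linear_predictor = eta))
  })
}

#' Write a simulated multifocal dataset to a directory
#'
#' @param sim result of [gen_multifocal_counts()].
#' @param dir output directory, created if missing.
#' @return the directory, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_expression(sim$expr, file.path(dir, "counts.tsv"))
  write_table_tsv(sim$annotation, file.path(dir, "annotation.tsv"))
  truth <- data.frame(key = c(rep("monotone_gene", length(sim$truth$monotone_gene_ids)),
                              rep("seeding_gene", length(sim$truth$seeding_gene_ids)),
                              rep("seeding_focus", length(sim$truth$seeding_focus_per_patient))),
                      id = c(sim$truth$monotone_gene_ids, sim$truth$seeding_gene_ids,
                             names(sim$truth$seeding_focus_per_patient)),
                      value = c(sim$truth$monotone_gene_ids, sim$truth$seeding_gene_ids,
                                unname(sim$truth$seeding_focus_per_patient)),
                      stringsAsFactors = FALSE)
  write_table_tsv(truth, file.path(dir, "truth.tsv"))
  invisible(dir)
}
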