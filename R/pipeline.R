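# Pipeline orchestration: simulate -> scan -> validate -> place -> fit ->
# date, driven by a single YAML (or list) configuration with an explicit
# seed.  Every stage writes plain-text artifacts so stages can be re-run
# independently; report headers record the seed and thresholds.

#' Branch-class assignment implied by loss placements
#'
#' Each loss event branch gets its own dN/dS class (`loss_<branch>`),
#' branches strictly below any event become `pseudogene`, everything else
#' stays `background` -- the class structure of a branch model with one
#' class per loss branch, a pseudogene class and a functional class.
#'
#' @param tree A [time_tree()].
#' @param event_branches Character vector of event-branch child labels.
#' @return Named character vector (branch label -> class).
#' @export
loss_branch_classes <- function(tree, event_branches) {
  out <- character(0)
  for (b in event_branches) {
    out[b] <- paste0("loss_", b)
    for (d in descendant_labels(tree, b)) out[d] <- "pseudogene"
  }
  out
}

#' Date a loss event from a fitted branch model
#'
#' Reads the functional-class and loss-branch dN/dS off a
#' [fit_branch_model()] fit with [loss_branch_classes()] classes, combines
#' them with the loss branch's divergence-date bounds and inverts the
#' mixture formula via [date_loss()].
#'
#' @param fit A fitted `branch_class_model`.
#' @param tree The [time_tree()].
#' @param branch Event-branch child label.
#' @param syn_scaling Functional-to-neutral synonymous rate ratio c.
#' @param parsimony_floor Optional minimum loss age (Mya).
#' @return A `loss_dating_result`.
#' @export
date_loss_event <- function(fit, tree, branch, syn_scaling = 0.7,
                            parsimony_floor = NULL) {
  cls <- paste0("loss_", branch)
  if (!cls %in% names(fit$omegas)) {
    stop("date_loss_event: fit has no class for branch '", branch, "'")
  }
  omega_f <- unname(fit$omegas[["background"]])
  omega_m <- unname(fit$omegas[[cls]])
  pa <- parent_label(tree, branch)
  if (is.na(pa)) stop("date_loss_event: cannot date a loss above the root")
  inputs <- dating_inputs(
    omega_mixed = omega_m, omega_functional = omega_f,
    syn_scaling = syn_scaling,
    start_older = node_date(tree, pa, "older"),
    start_younger = node_date(tree, pa, "younger"),
    end_older = node_date(tree, branch, "older"),
    end_younger = node_date(tree, branch, "younger"),
    parsimony_floor = parsimony_floor)
  date_loss(inputs)
}

#' Write the combined status/dating report
#'
#' One row per species status and one per dated loss event, in a stable
#' order; reruns on identical input produce byte-identical files.
#'
#' @param statuses List of [classify_status()] results (may be empty).
#' @param dating Named list of `loss_dating_result` (names = branches; may
#'   be empty).
#' @param path Output TSV path.
#' @param seed Seed recorded in the header comment.
#' @export
write_results <- function(statuses, dating, path, seed = NA) {
  cols <- c("record", "species", "status", "n_mutations",
            "fraction_ambiguous", "branch", "omega_functional",
            "omega_mixed", "syn_scaling", "t_functional", "t_pseudogenic",
            "loss_date_older", "loss_date_younger", "clamped_by_parsimony")
  rows <- list()
  for (s in statuses[order(vapply(statuses, `[[`, character(1), "species"))]) {
    rows[[length(rows) + 1L]] <- data.frame(
      record = "status", species = s$species, status = s$status,
      n_mutations = nrow(s$mutations),
      fraction_ambiguous = round(s$fraction_ambiguous, 4),
      branch = NA, omega_functional = NA, omega_mixed = NA,
      syn_scaling = NA, t_functional = NA, t_pseudogenic = NA,
      loss_date_older = NA, loss_date_younger = NA,
      clamped_by_parsimony = NA, stringsAsFactors = FALSE)
  }
  for (b in sort(names(dating))) {
    d <- dating[[b]]
    rows[[length(rows) + 1L]] <- data.frame(
      record = "dating", species = NA, status = NA, n_mutations = NA,
      fraction_ambiguous = NA, branch = b,
      omega_functional = round(d$inputs$omega_functional, 4),
      omega_mixed = round(d$inputs$omega_mixed, 4),
      syn_scaling = d$inputs$syn_scaling,
      t_functional = round(d$t_functional[["older"]], 3),
      t_pseudogenic = round(d$t_pseudogenic[["older"]], 3),
      loss_date_older = round(d$loss_date_older, 3),
      loss_date_younger = round(d$loss_date_younger, 3),
      clamped_by_parsimony = d$clamped_by_parsimony,
      stringsAsFactors = FALSE)
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# genelossr report; seed=", seed), con)
  df <- if (length(rows)) do.call(rbind, rows) else {
    as.data.frame(stats::setNames(rep(list(character(0)), length(cols)),
                                  cols))
  }
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

default_thresholds <- function() {
  list(min_reads = 30, flank = 50, missing_threshold = 0.2,
       syn_scaling = 0.7, breakpoint_tolerance = 2,
       het_band = c(0.35, 0.65), read_depth = 40, read_length = 100)
}

read_pipeline_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    if (!file.exists(config)) {
      stop("pipeline config file not found: ", config)
    }
    config <- yaml::read_yaml(config)
  }
  if (is.null(config$seed)) config$seed <- 1L
  th <- default_thresholds()
  th[names(config$thresholds)] <- config$thresholds
  config$thresholds <- th
  config
}

need_field <- function(config, field, where) {
  v <- config[[field]]
  if (is.null(v)) {
    stop("pipeline config error: missing field '", field, "' in ", where)
  }
  v
}

#' Run the simulation stage of the pipeline
#'
#' Builds a [simulation_config()] from the `simulate:` section of the
#' pipeline config, simulates the alignment, injects lesions, simulates
#' validation reads over every allele-discriminating lesion, and writes
#' `alignment.fa`, `gene_model.tsv`, `tree.nwk`, `truth.tsv` and
#' `reads/<species>_<position>.fa` into the output directory.
#'
#' @param config Pipeline config (list or YAML path) with fields `seed`,
#'   `output_dir` and a `simulate:` section (`tree` newick path or string,
#'   `n_codons`, `loss_events`, and optional simulator parameters).
#' @return Invisibly, the `list(alignments, truth, model)` simulation.
#' @export
run_simulate <- function(config) {
  config <- read_pipeline_config(config)
  sim_cfg <- need_field(config, "simulate", "config")
  out_dir <- need_field(config, "output_dir", "config")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  tree_spec <- need_field(sim_cfg, "tree", "simulate")
  tt <- if (file.exists(tree_spec)) {
    read_time_tree(tree_spec, calibrations = sim_cfg$calibrations)
  } else {
    time_tree(ape::read.tree(text = tree_spec),
              calibrations = sim_cfg$calibrations)
  }
  args <- list(tree = tt,
               n_codons = need_field(sim_cfg, "n_codons", "simulate"),
               loss_events = sim_cfg$loss_events %||% list(),
               seed = config$seed)
  for (f in c("omega_functional", "kappa", "syn_scaling", "neutral_rate",
              "n_exons", "intron_length", "reference")) {
    if (!is.null(sim_cfg[[f]])) args[[f]] <- sim_cfg[[f]]
  }
  if (!is.null(sim_cfg$lesion_rates)) {
    args$lesion_rates <- unlist(sim_cfg$lesion_rates)
  }
  cfg <- do.call(simulation_config, args)
  sim <- simulate_alignment(cfg)
  if (length(cfg$loss_events)) sim <- inject_lesions(sim)
  write_alignment(sim$alignments, file.path(out_dir, "alignment.fa"))
  write_gene_model(sim$model, file.path(out_dir, "gene_model.tsv"))
  ape::write.tree(tt$phy, file.path(out_dir, "tree.nwk"))
  tr <- sim$truth$lesions
  tr$seed <- rep(cfg$seed, nrow(tr))
  utils::write.table(tr, file.path(out_dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  reads_dir <- file.path(out_dir, "reads")
  dir.create(reads_dir, showWarnings = FALSE)
  th <- config$thresholds
  if (nrow(tr)) {
    disc <- tr[tr$ancestral_allele != tr$derived_allele, , drop = FALSE]
    for (k in seq_len(nrow(disc))) {
      m <- disc[k, ]
      reads <- tryCatch(
        simulate_reads(sim$alignments[[m$species]], m,
                       depth = th$read_depth,
                       read_length = th$read_length,
                       seed = cfg$seed + 1000L + k),
        error = function(e) NULL) # e.g. lesion too close to a sequence end
      if (is.null(reads)) next
      write_reads_fasta(reads, file.path(
        reads_dir, paste0(m$species, "_", m$position, ".fa")))
    }
  }
  invisible(sim)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full analysis pipeline
#'
#' Executes scan -> validate -> place -> fit -> date on the configured
#' inputs and writes `status.tsv`, `mutations.tsv`, `support.tsv`,
#' `omega.tsv`, `dating.tsv` and the combined `report.tsv` into the output
#' directory.
#'
#' @param config Pipeline config (list or YAML path) with `output_dir`,
#'   `seed`, optional `thresholds`, and an `analysis:` section naming
#'   `alignment`, `gene_model`, `tree`, `reference` and optionally
#'   `reads_dir` and `calibrations`.
#' @return A list with `statuses`, `mutations`, `support`, `placements`,
#'   `fit`, `dating`.
#' @export
run_full_analysis <- function(config) {
  config <- read_pipeline_config(config)
  an <- need_field(config, "analysis", "config")
  out_dir <- need_field(config, "output_dir", "config")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  th <- config$thresholds
  alns <- read_alignment(need_field(an, "alignment", "analysis"))
  model <- read_gene_model(need_field(an, "gene_model", "analysis"))
  tt <- read_time_tree(need_field(an, "tree", "analysis"),
                       calibrations = an$calibrations)
  ref_name <- need_field(an, "reference", "analysis")
  ref <- alns[[ref_name]]
  if (is.null(ref)) stop("reference species '", ref_name,
                         "' not in alignment")
  # scan + classify
  species <- intersect(tt$phy$tip.label, names(alns))
  statuses <- lapply(alns[species], function(a) {
    m <- scan_species(model, a, ref)
    classify_status(m, a, model, ref,
                    missing_threshold = th$missing_threshold)
  })
  mutations <- do.call(rbind, lapply(statuses, `[[`, "mutations"))
  hdr <- paste0("# genelossr; seed=", config$seed,
                "; min_reads=", th$min_reads,
                "; missing_threshold=", th$missing_threshold,
                "; syn_scaling=", th$syn_scaling)
  write_tsv_with_header <- function(df, file) {
    con <- file(file.path(out_dir, file), "w")
    on.exit(close(con))
    writeLines(hdr, con)
    utils::write.table(df, con, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  status_df <- data.frame(
    species = vapply(statuses, `[[`, character(1), "species"),
    status = vapply(statuses, `[[`, character(1), "status"),
    n_mutations = vapply(statuses, function(s) nrow(s$mutations),
                         integer(1)),
    fraction_ambiguous = round(vapply(statuses, `[[`, numeric(1),
                                      "fraction_ambiguous"), 4))
  status_df <- status_df[order(status_df$species), ]
  write_tsv_with_header(status_df, "status.tsv")
  if (!is.null(mutations) && nrow(mutations)) {
    write_tsv_with_header(
      mutations[order(mutations$species, mutations$position),
                c("species", "mclass", "exon_index", "position", "size",
                  "ancestral_allele", "derived_allele")],
      "mutations.tsv")
  }
  # validate against reads, where provided
  support <- NULL
  if (!is.null(an$reads_dir) && dir.exists(an$reads_dir) &&
      !is.null(mutations) && nrow(mutations)) {
    rows <- list()
    for (k in seq_len(nrow(mutations))) {
      m <- mutations[k, ]
      rf <- file.path(an$reads_dir, paste0(m$species, "_", m$position, ".fa"))
      if (!file.exists(rf)) next
      reads <- read_reads(rf)
      sup <- tryCatch(
        classify_support(
          count_support(extract_context(alns[[m$species]], m,
                                        flank = th$flank), reads),
          min_reads = th$min_reads, het_band = th$het_band),
        error = function(e) NULL)
      if (is.null(sup)) next
      rows[[length(rows) + 1L]] <- data.frame(
        species = m$species, mclass = m$mclass, position = m$position,
        n_derived = sup$n_derived, n_ancestral = sup$n_ancestral,
        n_other = sup$n_other, verdict = sup$verdict,
        stringsAsFactors = FALSE)
    }
    if (length(rows)) {
      support <- do.call(rbind, rows)
      support <- support[order(support$species, support$position), ]
      write_tsv_with_header(support, "support.tsv")
    }
  }
  # place loss events
  placements <- place_loss_events(statuses, tt,
                                  tolerance = th$breakpoint_tolerance)
  fit <- NULL
  dating <- list()
  if (length(placements)) {
    event_branches <- vapply(placements, `[[`, character(1), "event_branch")
    classes <- loss_branch_classes(tt, event_branches)
    seqs <- cds_alignment(alns, model, ref_name)
    fit <- fit_branch_model(seqs, tt, class_of_branch = classes)
    omega_df <- data.frame(class = names(fit$omegas),
                           omega = round(unname(fit$omegas), 4))
    write_tsv_with_header(omega_df, "omega.tsv")
    for (p in placements) {
      b <- p$event_branch
      floor_date <- if (!p$independent) node_date(tt, b) else NULL
      dating[[b]] <- tryCatch(
        date_loss_event(fit, tt, b, syn_scaling = th$syn_scaling,
                        parsimony_floor = floor_date),
        error = function(e) e)
    }
    ok <- !vapply(dating, inherits, logical(1), "error")
    if (any(ok)) {
      ddf <- do.call(rbind, lapply(names(dating)[ok], function(b) {
        d <- dating[[b]]
        data.frame(branch = b,
                   omega_functional = round(d$inputs$omega_functional, 4),
                   omega_mixed = round(d$inputs$omega_mixed, 4),
                   syn_scaling = d$inputs$syn_scaling,
                   t_functional = round(d$t_functional[["older"]], 3),
                   t_pseudogenic = round(d$t_pseudogenic[["older"]], 3),
                   loss_date_older = round(d$loss_date_older, 3),
                   loss_date_younger = round(d$loss_date_younger, 3),
                   clamped = d$clamped_by_parsimony)
      }))
      write_tsv_with_header(ddf, "dating.tsv")
    }
    write_results(statuses, dating[ok], file.path(out_dir, "report.tsv"),
                  seed = config$seed)
  } else {
    write_results(statuses, list(), file.path(out_dir, "report.tsv"),
                  seed = config$seed)
  }
  list(statuses = statuses, mutations = mutations, support = support,
       placements = placements, fit = fit, dating = dating)
}
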