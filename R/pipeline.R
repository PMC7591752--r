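# End-to-end orchestration: differential selection -> 12-method target
# scoring and validation -> best-method merged network -> biclique modules
# -> sponge scan + network -> MCL modules -> hubs -> optional enrichment.
# Every stage is a pure function of (inputs, config, seed); stage outputs
# and a manifest are written to the output directory with no timestamps,
# so identical runs are byte-identical.

#' Pipeline configuration
#'
#' Houses the printed constants of the workflow: top 100/300/4000
#' differential genes per class, validation cutoffs K in {50, 100, 150,
#' 200} (the merged network uses the largest), raw significance thresholds
#' 0.05, the SC grid 0.10-0.30 in steps of 0.05, hub fraction 20%, and
#' module minima of 3.
#'
#' @param top_mirna,top_lnc,top_mrna Differential genes kept per class.
#' @param topk_list Per-miRNA validation cutoffs.
#' @param merge_k Per-miRNA, per-class cutoff for the merged network
#'   (default `max(topk_list)`).
#' @param methods Prediction methods to compare.
#' @param p_share,p_corr Sponge sharing / positive-correlation thresholds.
#' @param sc_grid SC cutoffs scanned for power-law fit.
#' @param sc_cutoff Fixed SC cutoff; `NULL` (default) selects by scan.
#' @param min_shared Minimum shared miRNAs for a candidate sponge pair.
#' @param mcl_inflation MCL inflation exponent.
#' @param hub_fraction Top degree fraction kept as hubs.
#' @param min_biclique_left,min_biclique_right Biclique module minima.
#' @param min_sponge_module Minimum MCL module size.
#' @param seed Root seed for all randomised stages.
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(top_mirna = 100L, top_lnc = 300L, top_mrna = 4000L,
                            topk_list = c(50L, 100L, 150L, 200L),
                            merge_k = max(topk_list),
                            methods = all_methods,
                            p_share = 0.05, p_corr = 0.05,
                            sc_grid = seq(0.1, 0.3, by = 0.05),
                            sc_cutoff = NULL, min_shared = 1L,
                            mcl_inflation = 2, hub_fraction = 0.2,
                            min_biclique_left = 3L, min_biclique_right = 3L,
                            min_sponge_module = 3L, seed = 1L) {
  assert_scalar_number(p_share, "p_share", 1e-12, 1 - 1e-12)
  assert_scalar_number(p_corr, "p_corr", 1e-12, 1 - 1e-12)
  assert_scalar_number(hub_fraction, "hub_fraction", 1e-12, 1)
  if (!length(sc_grid) || any(diff(sc_grid) <= 0)) {
    abort("sc_grid must be an increasing vector of cutoffs")
  }
  methods <- match.arg(methods, all_methods, several.ok = TRUE)
  structure(as.list(environment()), class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose keys match [pipeline_config()] arguments;
#'   `sc_grid` may be given as `{low, high, step}`.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  vals <- yaml::read_yaml(path)
  if (is.list(vals$sc_grid) && all(c("low", "high", "step") %in% names(vals$sc_grid))) {
    g <- vals$sc_grid
    if (g$low >= g$high || g$step <= 0) abort("sc_grid needs low < high and step > 0")
    vals$sc_grid <- seq(g$low, g$high, by = g$step)
  }
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown)) {
    abort(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")))
  }
  do.call(pipeline_config, vals)
}

write_tsv_plain <- function(x, path) {
  df <- as.data.frame(x)
  num <- vapply(df, is.double, TRUE)
  df[num] <- lapply(df[num], function(v) sprintf("%.12g", v))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full stepwise pipeline
#'
#' Executes: (1) per-class moderated-t differential expression and top-N
#' selection; (2) miRNA-target scoring with the configured methods for
#' both target classes and validation against the ground-truth interaction
#' set over the K grid; (3) merged top-`merge_k` network of the
#' best-validated method; (4) maximal-biclique regulatory modules; (5)
#' SC-cutoff scan (power-law R-squared) and sponge network inference; (6)
#' MCL sponge modules; (7) hub miRNAs (regulatory network) and hub sponges
#' (sponge network); (8) optional over-representation analysis of sponge
#' modules. All stage tables plus a manifest are written under `out_dir`.
#'
#' @param sim A [simulate_cernet()] result, or `NULL` when reading from
#'   `input_paths`.
#' @param out_dir Output directory (created; files overwritten).
#' @param config A [pipeline_config()].
#' @param input_paths Named list of file paths (`mirna`, `lncrna`, `mrna`,
#'   `labels`, `interactions_lncrna`, `interactions_mrna`, `validated`)
#'   used when `sim` is `NULL`.
#' @param gene_sets Optional named list of gene sets (e.g.
#'   [read_gene_sets()]) for the enrichment stage.
#' @return Invisibly, the manifest list.
#' @export
run_pipeline <- function(sim = NULL, out_dir, config = pipeline_config(),
                         input_paths = NULL, gene_sets = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- "load inputs"
  manifest <- list(package_version = as.character(utils::packageVersion("cernet")),
                   seed = config$seed,
                   config = config[setdiff(names(config), "methods")],
                   methods = config$methods, stages = list())
  on.exit({
    manifest$failed_stage <- stage
    try(jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                             auto_unbox = TRUE, pretty = TRUE, digits = NA),
        silent = TRUE)
  })
  if (is.null(sim)) {
    if (is.null(input_paths)) abort("provide either `sim` or `input_paths`")
    mirna <- read_expression(input_paths$mirna, "miRNA", input_paths$labels)
    lnc <- read_expression(input_paths$lncrna, "lncRNA", input_paths$labels)
    mrna <- read_expression(input_paths$mrna, "mRNA", input_paths$labels)
    interactions <- bind_rows(
      read_interactions(input_paths$interactions_lncrna, "lncRNA"),
      read_interactions(input_paths$interactions_mrna, "mRNA")
    )
    validated <- bind_rows(
      read_interactions(input_paths$validated, "mRNA")[, 1:2]
    )
    manifest$input_checksums <- as.list(tools::md5sum(unlist(input_paths)))
  } else {
    stopifnot(inherits(sim, "cer_sim"))
    mirna <- sim$mirna
    lnc <- sim$lnc
    mrna <- sim$mrna
    interactions <- sim$interactions
    validated <- sim$truth$validated_interactions
    manifest$input_checksums <- list(simulation_seed = sim$config$seed)
  }
  check_alignment(mirna, lnc, mrna)

  # --- stage 1: differential expression + selection ---
  stage <- "differential expression"
  de <- list(miRNA = diff_expr(mirna), lncRNA = diff_expr(lnc),
             mRNA = diff_expr(mrna))
  tops <- c(miRNA = config$top_mirna, lncRNA = config$top_lnc,
            mRNA = config$top_mrna)
  sel <- purrr::imap(de, function(tab, cls) {
    select_top(tab, min(tops[[cls]], nrow(tab)))$gene_id
  })
  for (cls in names(de)) {
    write_tsv_plain(de[[cls]], file.path(out_dir, sprintf("de_%s.tsv", tolower(cls))))
  }
  mirna_s <- expr_subset(mirna, sel$miRNA)
  lnc_s <- expr_subset(lnc, sel$lncRNA)
  mrna_s <- expr_subset(mrna, sel$mRNA)
  manifest$stages$differential <- lapply(de, nrow)
  manifest$stages$selected <- lapply(sel, length)

  # --- stage 2: target scoring + validation ---
  stage <- "target scoring"
  classes <- list(lncRNA = lnc_s, mRNA = mrna_s)
  scores <- list()
  for (mth in config$methods) {
    for (cls in names(classes)) {
      mask <- filter(interactions, .data$target_class == cls)
      sm <- score_targets(
        mirna_s, classes[[cls]], method = mth, target_class = cls,
        candidate_mask = if (mth == "promise") mask else NULL,
        seed = derive_seed(config$seed, 10L + match(mth, all_methods))
      )
      scores[[paste(mth, cls, sep = ".")]] <- sm
      write_tsv_plain(tidy(sm),
                      file.path(out_dir, sprintf("scores_%s_%s.tsv", mth, tolower(cls))))
    }
  }
  stage <- "validation"
  topk <- pmin(config$topk_list,
               min(nrow(lnc_s$values), nrow(mrna_s$values)))
  topk <- unique(topk)
  validation <- validate_methods(scores, validated, topk)
  write_tsv_plain(validation, file.path(out_dir, "validation.tsv"))
  best <- best_method(validation)
  manifest$stages$validation <- list(best_method = best,
                                     k_grid = as.integer(topk))

  # --- stage 3: merged network of the best method ---
  stage <- "merged network"
  best_scores <- scores[paste(best, names(classes), sep = ".")]
  network <- build_target_network(best_scores,
                                  min(config$merge_k,
                                      min(nrow(lnc_s$values), nrow(mrna_s$values))))
  write_tsv_plain(network, file.path(out_dir, "network_edges.tsv"))
  write_edges(network[, c("mirna_id", "target_id", "score")],
              file.path(out_dir, "network_edges.graphml"), format = "graphml")
  manifest$stages$network <- list(n_edges = nrow(network))

  # --- stage 4: biclique modules ---
  stage <- "biclique modules"
  modules <- enumerate_maximal_bicliques(network,
                                         min_mirnas = config$min_biclique_left,
                                         min_targets = config$min_biclique_right)
  write_tsv_plain(modules, file.path(out_dir, "biclique_modules.tsv"))
  manifest$stages$bicliques <- list(n_modules = nrow(modules))

  # --- stage 5: sponge scan + network ---
  stage <- "sponge network"
  scan <- scan_sc_cutoff(mirna_s, lnc_s, mrna_s, interactions,
                         cutoffs = config$sc_grid,
                         p_share_max = config$p_share,
                         p_corr_max = config$p_corr,
                         min_shared = config$min_shared)
  write_tsv_plain(tidy(scan), file.path(out_dir, "sc_scan.tsv"))
  sc_cut <- config$sc_cutoff %||% scan$selected
  sponge <- filter(scan$edges, .data$sc >= sc_cut)
  write_tsv_plain(sponge, file.path(out_dir, "sponge_edges.tsv"))
  manifest$stages$sponge <- list(sc_cutoff = sc_cut, n_edges = nrow(sponge))

  # --- stage 6: MCL sponge modules ---
  stage <- "sponge modules"
  sponge_modules <- if (nrow(sponge)) {
    mcl_cluster(sponge[, c("rna_i", "rna_j", "sc")],
                inflation = config$mcl_inflation,
                min_size = config$min_sponge_module)
  } else {
    tibble(module_id = integer(), member = character(), module_size = integer())
  }
  write_tsv_plain(sponge_modules, file.path(out_dir, "sponge_modules.tsv"))
  manifest$stages$sponge_modules <-
    list(n_modules = length(unique(sponge_modules$module_id)))

  # --- stage 7: hubs ---
  stage <- "hub selection"
  hub_mirnas <- select_hubs(network[, c("mirna_id", "target_id")],
                            fraction = config$hub_fraction,
                            nodes = gene_ids(mirna_s))
  hub_sponges <- if (nrow(sponge)) {
    select_hubs(sponge[, c("rna_i", "rna_j")], fraction = config$hub_fraction)
  } else {
    tibble(node = character(), degree = integer())
  }
  hubs <- bind_rows(mutate(hub_mirnas, hub_type = "miRNA"),
                    mutate(hub_sponges, hub_type = "sponge"))
  write_tsv_plain(hubs, file.path(out_dir, "hubs.tsv"))
  manifest$stages$hubs <- list(n_hub_mirnas = nrow(hub_mirnas),
                               n_hub_sponges = nrow(hub_sponges))

  # --- stage 8: optional enrichment ---
  stage <- "enrichment"
  if (!is.null(gene_sets) && nrow(sponge_modules)) {
    universe <- c(gene_ids(mirna), gene_ids(lnc), gene_ids(mrna))
    enr <- purrr::map_dfr(split(sponge_modules$member, sponge_modules$module_id),
                          function(members) ora(members, universe, gene_sets),
                          .id = "module_id")
    write_tsv_plain(enr, file.path(out_dir, "enrichment.tsv"))
    manifest$stages$enrichment <- list(n_tests = nrow(enr))
  }

  stage <- NULL
  on.exit()
  manifest$failed_stage <- NULL
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
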