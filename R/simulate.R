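# Seeded linear-Gaussian generator of matched miRNA / lncRNA / mRNA
# expression with planted structure for every pipeline stage:
#   * differential genes: mean shift delta on the case group;
#   * regulation: target = beta * miRNA + noise, beta < 0 (repression);
#   * sponge components: small cliques of genes driven by a shared triple
#     of miRNAs, giving within-component pair correlation == sc and
#     sensitivity correlation == sc (the shared miRNAs explain all of it);
#   * decoy putative interactions with no expression effect.
#
# Components can be "pinned": their miRNA and residual sample vectors are
# drawn from an exactly orthonormal, exactly zero-mean basis, so empirical
# correlations equal the nominal ones to machine precision and the planted
# SC-cutoff structure is immune to finite-sample noise. Unpinned components
# use iid Gaussian draws and converge at the usual 1/sqrt(m) rate.

default_components <- function() {
  tibble(
    n_genes = c(4L, rep(3L, 2), 3L, rep(2L, 14), rep(2L, 4), rep(3L, 8)),
    sc = c(rep(0.5, 3), 0.28, rep(0.5, 14), rep(0.28, 4), rep(0.16, 8)),
    role = c(rep("backbone", 3), "weak", rep("backbone", 14),
             rep("weak", 4), rep("noise", 8))
  )
}

#' Configuration for the synthetic-data generator
#'
#' @param seed Root RNG seed (determines everything).
#' @param m_case,m_control Sample counts per group (the study sizes are
#'   104 and 82).
#' @param pool_size miRNA pool from which sponge components draw their
#'   shared triples (triples overlap pairwise in at most one miRNA, so
#'   cross-component gene pairs never pass the sharing test).
#' @param n_mirna_null,n_lnc_decoy,n_mrna_decoy Unplanted genes per class.
#' @param n_reg_lnc,n_reg_mrna Regulated targets per class (one dedicated
#'   miRNA each).
#' @param beta Planted regulation effect (must be negative: repression).
#' @param noise_sd Residual sd of regulated targets.
#' @param delta Case-group mean shift of planted differential genes
#'   (regulation miRNAs; their targets inherit `beta * delta`).
#' @param target_baseline Constant added to regulated targets (used by
#'   allocation-based scoring, which ranks by mean expression).
#' @param confounders_per_mirna Per regulation miRNA, extra targets
#'   correlated with it (`confounder_beta`) but absent from the putative
#'   interaction table and the ground truth.
#' @param confounder_beta Effect size of confounder targets.
#' @param components Tibble (`n_genes`, `sc`, `role`) of sponge
#'   components; each is a clique of `n_genes` genes sharing one miRNA
#'   triple with within-pair correlation and sensitivity correlation `sc`.
#' @param pin_components Pin component factors (see file header).
#' @param decoys_per_target False putative regulators added per target.
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       m_case = 104L, m_control = 82L,
                       pool_size = 19L,
                       n_mirna_null = 6L, n_lnc_decoy = 14L, n_mrna_decoy = 26L,
                       n_reg_lnc = 5L, n_reg_mrna = 10L,
                       beta = -0.8, noise_sd = 0.6, delta = 0.6,
                       target_baseline = 0,
                       confounders_per_mirna = 0L, confounder_beta = -1.3,
                       components = default_components(),
                       pin_components = TRUE,
                       decoys_per_target = 2L) {
  if (beta > 0) abort("`beta` must be <= 0 (miRNAs repress their targets; 0 plants a null)")
  if (m_case + m_control < 20L) abort("need m_samples >= 20")
  if (any(components$sc >= 1)) {
    abort(sprintf(
      "infeasible sponge sc >= 1: the linear model attains at most %.4f",
      1 - 1e-6))
  }
  if (any(components$sc <= 0)) abort("component sc must be in (0, 1)")
  structure(as.list(environment()), class = "sim_config")
}

#' Small preset: the desk-scale study configuration
#'
#' 40 miRNAs, 55 lncRNAs, 73 mRNAs over 104 + 82 samples; 15 planted
#' regulations and 30 pinned sponge components whose exact SC levels
#' (0.5 backbone / 0.28 weak / 0.16 noise) plant 0.25 as the
#' power-law-optimal SC cutoff on the default 0.10-0.30 grid.
#'
#' @param seed Root seed.
#' @export
sim_config_small <- function(seed = 1L) sim_config(seed = seed)

#' Paper-shaped preset: full-size matrices
#'
#' Same planted structure as the small preset but padded with null genes
#' to 120 miRNAs, 360 lncRNAs and 4,400 mRNAs over 104 + 82 samples, so
#' top-100/300/4000 differential selection is a real subsetting step.
#'
#' @param seed Root seed.
#' @export
sim_config_paper <- function(seed = 1L) {
  sim_config(seed = seed, n_mirna_null = 86L, n_lnc_decoy = 319L,
             n_mrna_decoy = 4353L)
}

# Greedy packing of miRNA triples with pairwise overlap <= 1.
pack_triples <- function(pool, n_needed) {
  if (n_needed == 0L) return(list())
  cand <- utils::combn(length(pool), 3L, simplify = FALSE)
  kept <- list()
  for (tr in cand) {
    ok <- all(vapply(kept, function(k) length(intersect(k, tr)) <= 1L, TRUE))
    if (ok) kept[[length(kept) + 1L]] <- tr
    if (length(kept) == n_needed) break
  }
  if (length(kept) < n_needed) {
    abort(sprintf("miRNA pool of %d supports only %d low-overlap triples (need %d); increase pool_size",
                  length(pool), length(kept), n_needed))
  }
  lapply(kept, function(idx) pool[idx])
}

# m x f matrix whose columns are exactly zero-mean, exactly orthogonal,
# with sample variance exactly 1.
orthonormal_factors <- function(m, f) {
  if (f > m - 1L) {
    abort(sprintf("cannot pin %d factors with %d samples (need factors <= samples - 1)", f, m))
  }
  x <- matrix(rnorm(m * f), m, f)
  x <- sweep(x, 2, colMeans(x))
  q <- qr.Q(qr(x))
  q <- sweep(q, 2, colMeans(q)) # centered subspace; re-center for safety
  q * sqrt(m - 1)
}

#' Generate a synthetic matched-expression study
#'
#' Draws the expression matrices, the putative interaction tables and the
#' ground truth described by a [sim_config()]. The same seed always yields
#' byte-identical output.
#'
#' @param config A `sim_config`.
#' @return A `cer_sim` list: `mirna`, `lnc`, `mrna` ([cer_expr] objects),
#'   `interactions` (putative pairs, both classes), `truth` (list with
#'   `regulation`, `confounders`, `sponge_pairs`, `differential`), and
#'   `config`.
#' @export
simulate_cernet <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  cf <- config
  with_seed(cf$seed, {
    m <- cf$m_case + cf$m_control
    g_ind <- c(rep(1, cf$m_case), rep(0, cf$m_control))
    samples <- tibble(
      sample_id = sprintf("s%03d", seq_len(m)),
      group = ifelse(g_ind == 1, "case", "control")
    )
    n_reg <- cf$n_reg_lnc + cf$n_reg_mrna
    n_comp <- nrow(cf$components)
    comp_sizes <- cf$components$n_genes
    n_sponge <- sum(comp_sizes)
    mir_ids <- sprintf("mir%03d", seq_len(cf$pool_size + n_reg + cf$n_mirna_null))
    pool_ids <- mir_ids[seq_len(cf$pool_size)]
    reg_mir_ids <- mir_ids[cf$pool_size + seq_len(n_reg)]
    triples <- pack_triples(pool_ids, n_comp)

    # --- miRNA expression ---
    if (cf$pin_components) {
      fac <- orthonormal_factors(m, cf$pool_size + n_sponge)
      z_pool <- fac[, seq_len(cf$pool_size), drop = FALSE]
      resid_fac <- fac[, cf$pool_size + seq_len(n_sponge), drop = FALSE]
    } else {
      z_pool <- matrix(rnorm(m * cf$pool_size), m)
      resid_fac <- matrix(rnorm(m * n_sponge), m)
    }
    colnames(z_pool) <- pool_ids
    reg_signs <- sample(c(-1, 1), n_reg, replace = TRUE)
    z_reg <- matrix(rnorm(m * n_reg), m) +
      outer(g_ind, reg_signs) * cf$delta
    z_null <- matrix(rnorm(m * cf$n_mirna_null), m)
    mirna_mat <- t(cbind(z_pool, z_reg, z_null))
    dimnames(mirna_mat) <- list(mir_ids, samples$sample_id)

    # --- sponge component genes ---
    comp_of_gene <- rep(seq_len(n_comp), comp_sizes)
    sponge_vals <- matrix(0, m, n_sponge)
    for (g in seq_len(n_sponge)) {
      comp <- comp_of_gene[g]
      s <- cf$components$sc[comp]
      cc <- sqrt(s / 3)
      shared <- rowSums(z_pool[, triples[[comp]], drop = FALSE])
      sponge_vals[, g] <- -cc * shared + sqrt(1 - s) * resid_fac[, g]
    }

    # --- regulated targets (+ confounders) ---
    reg_vals <- matrix(0, m, n_reg)
    for (r in seq_len(n_reg)) {
      reg_vals[, r] <- cf$target_baseline + cf$beta * z_reg[, r] +
        cf$noise_sd * rnorm(m)
    }
    n_conf <- cf$confounders_per_mirna * n_reg
    conf_vals <- matrix(0, m, n_conf)
    conf_owner <- integer(0)
    if (n_conf) {
      conf_owner <- rep(seq_len(n_reg), each = cf$confounders_per_mirna)
      for (q in seq_len(n_conf)) {
        conf_vals[, q] <- cf$confounder_beta * z_reg[, conf_owner[q]] +
          cf$noise_sd * rnorm(m)
      }
    }

    # --- class assignment ---
    sponge_class <- rep(c("lncRNA", "mRNA"), length.out = n_sponge)
    n_lnc <- sum(sponge_class == "lncRNA") + cf$n_reg_lnc + cf$n_lnc_decoy +
      ceiling(n_conf / 2)
    n_mrna <- sum(sponge_class == "mRNA") + cf$n_reg_mrna + cf$n_mrna_decoy +
      floor(n_conf / 2)
    lnc_ids <- sprintf("lnc%03d", seq_len(n_lnc))
    mrna_ids <- sprintf("rna%04d", seq_len(n_mrna))
    next_lnc <- 1L
    next_mrna <- 1L
    take_id <- function(cls) {
      if (cls == "lncRNA") {
        id <- lnc_ids[next_lnc]
        next_lnc <<- next_lnc + 1L
      } else {
        id <- mrna_ids[next_mrna]
        next_mrna <<- next_mrna + 1L
      }
      id
    }
    sponge_ids <- vapply(sponge_class, take_id, "")
    reg_class <- rep(c("lncRNA", "mRNA"), c(cf$n_reg_lnc, cf$n_reg_mrna))
    reg_ids <- vapply(reg_class, take_id, "")
    conf_class <- rep(c("lncRNA", "mRNA"), length.out = n_conf)
    conf_ids <- if (n_conf) vapply(conf_class, take_id, "") else character(0)
    decoy_class <- rep(c("lncRNA", "mRNA"), c(cf$n_lnc_decoy, cf$n_mrna_decoy))
    decoy_ids <- vapply(decoy_class, take_id, "")
    decoy_vals <- matrix(rnorm(m * length(decoy_ids)), m)

    target_ids <- c(sponge_ids, reg_ids, conf_ids, decoy_ids)
    target_class <- c(sponge_class, reg_class, conf_class, decoy_class)
    target_vals <- cbind(sponge_vals, reg_vals, conf_vals, decoy_vals)
    colnames(target_vals) <- target_ids

    build_expr <- function(cls, mat, ids) {
      vals <- t(mat[, ids, drop = FALSE])
      colnames(vals) <- samples$sample_id
      df <- data.frame(gene_id = ids, vals, check.names = FALSE)
      cer_expr(df, gene_class = cls, groups = samples)
    }
    lnc <- build_expr("lncRNA", target_vals, target_ids[target_class == "lncRNA"])
    mrna <- build_expr("mRNA", target_vals, target_ids[target_class == "mRNA"])
    mirna <- cer_expr(data.frame(gene_id = mir_ids, mirna_mat,
                                 check.names = FALSE),
                     gene_class = "miRNA", groups = samples)

    # --- putative interactions: component triples + regulations + decoys ---
    true_int <- bind_rows(
      tibble(mirna_id = unlist(lapply(comp_of_gene, function(cp) triples[[cp]])),
             target_id = rep(sponge_ids, each = 3L)),
      tibble(mirna_id = reg_mir_ids, target_id = reg_ids)
    )
    non_conf_targets <- c(sponge_ids, reg_ids, decoy_ids)
    decoy_int <- purrr::map_dfr(non_conf_targets, function(tid) {
      have <- true_int$mirna_id[true_int$target_id == tid]
      pickable <- setdiff(mir_ids, have)
      tibble(mirna_id = sample(pickable, min(cf$decoys_per_target,
                                             length(pickable))),
             target_id = tid)
    })
    class_of <- setNames(target_class, target_ids)
    interactions <- distinct(bind_rows(true_int, decoy_int))
    interactions$target_class <- unname(class_of[interactions$target_id])
    interactions <- arrange(interactions, .data$mirna_id, .data$target_id)

    # --- ground truth ---
    sponge_pairs <- purrr::map_dfr(seq_len(n_comp), function(cp) {
      ids <- sponge_ids[comp_of_gene == cp]
      if (length(ids) < 2L) return(NULL)
      prs <- utils::combn(ids, 2L)
      bind_rows(lapply(seq_len(ncol(prs)), function(i) {
        op <- order_pair(prs[1, i], prs[2, i])
        tibble(rna_i = op$rna_i, rna_j = op$rna_j,
               sc = cf$components$sc[cp], n_shared = 3L,
               role = cf$components$role[cp], component = cp)
      }))
    })
    validated <- true_int
    validated$target_class <- unname(class_of[validated$target_id])
    truth <- list(
      validated_interactions = validated,
      regulation = tibble(mirna_id = reg_mir_ids, target_id = reg_ids,
                          target_class = reg_class, beta = cf$beta),
      confounders = tibble(mirna_id = reg_mir_ids[conf_owner],
                           target_id = conf_ids,
                           beta = cf$confounder_beta),
      sponge_pairs = sponge_pairs,
      differential = tibble(
        gene_id = c(reg_mir_ids, reg_ids),
        gene_class = c(rep("miRNA", n_reg), reg_class),
        delta = c(cf$delta * reg_signs, cf$beta * cf$delta * reg_signs)
      )
    )
    structure(list(mirna = mirna, lnc = lnc, mrna = mrna,
                   interactions = interactions, truth = truth,
                   config = cf),
              class = "cer_sim")
  })
}

#' @export
print.cer_sim <- function(x, ...) {
  cat(sprintf(
    "<cer_sim> %d miRNA / %d lncRNA / %d mRNA x %d samples; %d putative pairs, %d planted regulations, %d planted sponge pairs\n",
    nrow(x$mirna$values), nrow(x$lnc$values), nrow(x$mrna$values),
    ncol(x$mirna$values), nrow(x$interactions),
    nrow(x$truth$regulation), nrow(x$truth$sponge_pairs)))
  invisible(x)
}

#' Write a simulated study to disk in the canonical formats
#'
#' Emits the three expression TSVs, the sample label TSV, per-class
#' putative interaction TSVs, and the ground-truth tables.
#'
#' @param sim A [simulate_cernet()] result.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the named vector of written paths.
#' @export
write_simulation <- function(sim, dir) {
  stopifnot(inherits(sim, "cer_sim"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    mirna = file.path(dir, "mirna.tsv"),
    lncrna = file.path(dir, "lncrna.tsv"),
    mrna = file.path(dir, "mrna.tsv"),
    labels = file.path(dir, "labels.tsv"),
    interactions_lncrna = file.path(dir, "interactions_lncrna.tsv"),
    interactions_mrna = file.path(dir, "interactions_mrna.tsv"),
    truth_regulation = file.path(dir, "truth_regulation.tsv"),
    truth_sponge = file.path(dir, "truth_sponge.tsv")
  )
  write_expression(sim$mirna, paths["mirna"], labels_path = paths["labels"])
  write_expression(sim$lnc, paths["lncrna"])
  write_expression(sim$mrna, paths["mrna"])
  write_interactions(filter(sim$interactions, .data$target_class == "lncRNA"),
                     paths["interactions_lncrna"])
  write_interactions(filter(sim$interactions, .data$target_class == "mRNA"),
                     paths["interactions_mrna"])
  utils::write.table(sim$truth$regulation, paths["truth_regulation"],
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(sim$truth$sponge_pairs, paths["truth_sponge"],
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(paths)
}
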