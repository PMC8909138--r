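#' Simulation configuration
#'
#' Defines the synthetic study conditions: a 1091-cell TPM matrix (the size
#' of the malignant-cell compartment the pipeline is designed for) with
#' planted lipid-program (slow-cycling), cycling, and marker-high cells,
#' bulk mixtures of two population profiles, and survival times whose hazard
#' grows with the slow-cycling fraction.
#'
#' Defaults: 2000 genes with lognormal(meanlog 0, sdlog 1) baseline TPM,
#' columns renormalised to a constant total; 50 lipid-program genes elevated
#' by +3 log2 units in 22 planted slow-cycling cells; 40 G1S and 40 G2M
#' genes at +2 log2 in 22 planted cyclers; one marker gene per population
#' (CD133, SOX2, PTPRZ1, ITGB8, CD44) at +8 log2 in 22 planted cells each —
#' a single-gene ranking needs a large shift to dominate the lognormal
#' baseline tail across ~1100 cells.
#'
#' @param n_cells,n_genes Matrix dimensions.
#' @param seed Integer seed; every generator is a pure function of (config,
#'   seed).
#' @param n_scc,n_fcc,n_marker_high Planted population sizes.
#' @param n_lipid_genes,n_g1s_genes,n_g2m_genes Program sizes.
#' @param lipid_effect,cycle_effect,marker_effect Planted log2 shifts.
#' @param markers Marker gene names.
#' @param baseline_meanlog,baseline_sdlog Lognormal baseline parameters.
#' @param column_sum Per-cell TPM total after renormalisation.
#' @param n_bulk,bulk_noise_sd Bulk mixture count and per-gene lognormal
#'   noise sd (on the log scale).
#' @param surv_h0,surv_beta,censor_rate Baseline hazard, log-hazard
#'   coefficient on the SCC fraction, and censoring probability.
#' @return A validated list of class `SimConfig`.
#' @export
sim_config <- function(n_cells = 1091, n_genes = 2000, seed = 1L,
                       n_scc = 22, n_fcc = 22, n_marker_high = 22,
                       n_lipid_genes = 50, n_g1s_genes = 40,
                       n_g2m_genes = 40,
                       lipid_effect = 3, cycle_effect = 2, marker_effect = 8,
                       markers = c("CD133", "SOX2", "PTPRZ1", "ITGB8",
                                   "CD44"),
                       baseline_meanlog = 0, baseline_sdlog = 1,
                       column_sum = 1e6,
                       n_bulk = 50, bulk_noise_sd = 0.2,
                       surv_h0 = 0.002, surv_beta = 1.5,
                       censor_rate = 0.2) {
  cfg <- as.list(environment())
  n_planted <- n_scc + n_fcc + length(markers) * n_marker_high
  if (n_planted > n_cells)
    stop("planted populations (", n_planted, ") exceed n_cells (", n_cells,
         ")")
  n_prog <- n_lipid_genes + n_g1s_genes + n_g2m_genes + length(markers)
  if (n_prog > n_genes)
    stop("program genes (", n_prog, ") exceed n_genes (", n_genes, ")")
  if (censor_rate < 0 || censor_rate >= 1) stop("censor_rate must be in [0, 1)")
  structure(cfg, class = "SimConfig")
}

#' Simulate a single-cell TPM matrix with planted populations
#'
#' Baseline abundances are lognormal; planted slow-cycling cells have all
#' lipid-program genes multiplied by 2^lipid_effect, planted cyclers have
#' the G1S and G2M programs elevated, and each marker-high population has
#' its single marker gene elevated. All planted populations are pairwise
#' disjoint. Columns are renormalised to a constant TPM total.
#'
#' @param cfg A [sim_config()].
#' @return List with `matrix` (an `ExpressionMatrix`, TPM), `truth` (a
#'   data.frame of cell_id and planted population, "background" otherwise),
#'   `gene_programs` (data.frame gene_id/program), and `gene_sets` (a
#'   `GeneSetCollection` with the lipid, G1S and G2M programs).
#' @export
simulate_cells <- function(cfg) {
  stopifnot(inherits(cfg, "SimConfig"))
  set.seed(cfg$seed)
  n_g <- cfg$n_genes; n_c <- cfg$n_cells
  n_prog_genes <- cfg$n_lipid_genes + cfg$n_g1s_genes + cfg$n_g2m_genes
  gene_names <- c(sprintf("G%05d", seq_len(n_g - length(cfg$markers))),
                  cfg$markers)
  cell_names <- sprintf("cell_%04d", seq_len(n_c))
  lipid_genes <- gene_names[seq_len(cfg$n_lipid_genes)]
  g1s_genes <- gene_names[cfg$n_lipid_genes + seq_len(cfg$n_g1s_genes)]
  g2m_genes <- gene_names[cfg$n_lipid_genes + cfg$n_g1s_genes +
                            seq_len(cfg$n_g2m_genes)]
  program <- rep("background", n_g)
  names(program) <- gene_names
  program[lipid_genes] <- "lipid"
  program[g1s_genes] <- "G1S"
  program[g2m_genes] <- "G2M"
  program[cfg$markers] <- paste0("marker_", cfg$markers)

  vals <- matrix(stats::rlnorm(n_g * n_c, cfg$baseline_meanlog,
                               cfg$baseline_sdlog),
                 n_g, n_c, dimnames = list(gene_names, cell_names))

  pops <- c("SCC", "FCC", cfg$markers)
  sizes <- c(cfg$n_scc, cfg$n_fcc,
             rep(cfg$n_marker_high, length(cfg$markers)))
  picks <- sample(cell_names, sum(sizes))
  split_idx <- rep(pops, sizes)
  planted <- split(picks, factor(split_idx, levels = pops))
  truth <- data.frame(cell_id = cell_names, population = "background",
                      stringsAsFactors = FALSE)
  for (p in pops)
    truth$population[truth$cell_id %in% planted[[p]]] <- p

  vals[lipid_genes, planted$SCC] <-
    vals[lipid_genes, planted$SCC] * 2^cfg$lipid_effect
  vals[c(g1s_genes, g2m_genes), planted$FCC] <-
    vals[c(g1s_genes, g2m_genes), planted$FCC] * 2^cfg$cycle_effect
  for (mk in cfg$markers)
    vals[mk, planted[[mk]]] <- vals[mk, planted[[mk]]] * 2^cfg$marker_effect

  vals <- sweep(vals, 2, colSums(vals), "/") * cfg$column_sum

  gs <- gene_set_collection(list(
    gene_set("lipid_metabolism", lipid_genes),
    gene_set("G1S", g1s_genes),
    gene_set("G2M", g2m_genes)))
  list(matrix = expression_matrix(vals, "TPM"),
       truth = truth,
       gene_programs = data.frame(gene_id = gene_names, program = program,
                                  row.names = NULL),
       gene_sets = gs)
}

#' Deterministic fixture reproducing the printed overlap structure
#'
#' Seven groups of 22 synthetic cells (SCC, FCC and the five marker-high
#' groups) realising exactly the reported pairwise intersections:
#' PTPRZ1/CD44 share 3 cells, CD133/SOX2 share 2, and each of CD133/ITGB8,
#' SOX2/ITGB8, PTPRZ1/ITGB8, ITGB8/CD44, CD133/FCC and ITGB8/FCC shares 1;
#' SCC is disjoint from every other group; no cell belongs to three or more
#' groups. The implied private counts are SCC 22, FCC 20, SOX2 19, CD133 18,
#' PTPRZ1 18, CD44 18, ITGB8 17, and the multi-marker combination population
#' has 9 cells.
#'
#' @return Named list of 7 `CellGroup`s (SCC, FCC, CD133, SOX2, PTPRZ1,
#'   ITGB8, CD44).
#' @export
printed_overlap_fixture <- function() {
  shared_spec <- list(
    c("PTPRZ1", "CD44", 3),
    c("CD133", "SOX2", 2),
    c("CD133", "ITGB8", 1),
    c("SOX2", "ITGB8", 1),
    c("PTPRZ1", "ITGB8", 1),
    c("ITGB8", "CD44", 1),
    c("CD133", "FCC", 1),
    c("ITGB8", "FCC", 1))
  group_names <- c("SCC", "FCC", "CD133", "SOX2", "PTPRZ1", "ITGB8", "CD44")
  members <- stats::setNames(rep(list(character()), 7), group_names)
  counter <- 0L
  next_cells <- function(k) {
    ids <- sprintf("fix_%03d", counter + seq_len(k))
    counter <<- counter + k
    ids
  }
  for (sp in shared_spec) {
    ids <- next_cells(as.integer(sp[[3]]))
    members[[sp[[1]]]] <- c(members[[sp[[1]]]], ids)
    members[[sp[[2]]]] <- c(members[[sp[[2]]]], ids)
  }
  for (g in group_names)
    members[[g]] <- c(members[[g]], next_cells(22 - length(members[[g]])))
  kinds <- c(SCC = "signature", FCC = "cycle", CD133 = "marker",
             SOX2 = "marker", PTPRZ1 = "marker", ITGB8 = "marker",
             CD44 = "marker")
  out <- lapply(group_names, function(g) {
    score <- stats::setNames(seq(2, 1, length.out = 22), members[[g]])
    cell_group(g, members[[g]], score,
               selector = list(kind = unname(kinds[[g]]), source = g,
                               fraction = 0.02))
  })
  stats::setNames(out, group_names)
}

#' Simulate bulk mixtures of two population profiles
#'
#' Each bulk sample is f * profile_1 + (1 - f) * profile_2 with f drawn
#' Uniform(0, 1), multiplied per gene by exp(Normal(0, noise_sd)).
#'
#' @param cfg A [sim_config()] (uses `n_bulk`, `bulk_noise_sd`, `seed`).
#' @param profiles Genes x 2 matrix of population mean profiles (columns
#'   named, e.g. SCC and FCC).
#' @return List with `bulk` (an `ExpressionMatrix`, TPM) and `fractions`
#'   (named numeric: the planted fraction of the first profile).
#' @export
simulate_bulk <- function(cfg, profiles) {
  stopifnot(inherits(cfg, "SimConfig"), is.matrix(profiles),
            ncol(profiles) == 2)
  set.seed(cfg$seed + 1L)
  n <- cfg$n_bulk
  f <- stats::runif(n)
  sample_names <- sprintf("bulk_%03d", seq_len(n))
  vals <- vapply(seq_len(n), function(i) {
    mu <- f[i] * profiles[, 1] + (1 - f[i]) * profiles[, 2]
    mu * exp(stats::rnorm(nrow(profiles), 0, cfg$bulk_noise_sd))
  }, numeric(nrow(profiles)))
  dimnames(vals) <- list(rownames(profiles), sample_names)
  list(bulk = expression_matrix(vals, "TPM"),
       fractions = stats::setNames(f, sample_names))
}

#' Simulate survival times driven by a per-sample fraction
#'
#' Event times are exponential with hazard h0 * exp(beta * fraction).
#' Censoring is non-informative: each sample is censored with probability
#' `censor_rate`, and a censored sample's observed time is drawn uniformly
#' on (0, its event time).
#'
#' @param fractions Named numeric vector of per-sample fractions.
#' @param cfg A [sim_config()] (uses `surv_h0`, `surv_beta`, `censor_rate`,
#'   `seed`).
#' @return A `SurvivalRecords` data.frame (stratum "all").
#' @export
simulate_survival <- function(fractions, cfg) {
  stopifnot(inherits(cfg, "SimConfig"), all(is.finite(fractions)))
  set.seed(cfg$seed + 2L)
  n <- length(fractions)
  hazard <- cfg$surv_h0 * exp(cfg$surv_beta * fractions)
  t_event <- stats::rexp(n, rate = hazard)
  censored <- stats::rbinom(n, 1, cfg$censor_rate) == 1
  obs_time <- ifelse(censored, stats::runif(n) * t_event, t_event)
  survival_records(names(fractions), obs_time,
                   event = as.integer(!censored))
}
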