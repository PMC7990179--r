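#' Parameters for the bulk FPKM simulator
#'
#' The generator emulates the study's bulk design: two FACS populations
#' (reporter-positive preplate/Cajal-Retzius cells vs reporter-negative
#' progenitors) at three embryonic stages with two biological replicates.
#' Each gene is planted into one of the 27 temporal classes; the
#' reporter-negative mean FPKM is log-normal and constant across stages
#' (the progenitor baseline), and the positive-population mean at each
#' stage realises a pos/neg ratio drawn uniformly from the planted state's
#' ratio range. Ratios are planted on the pseudocounted scale used by
#' [compute_stage_ratio()], so at zero replicate noise the observed
#' per-stage ratio equals the planted one exactly.
#'
#' @param n_replicates Biological replicates per population x stage.
#' @param class_probabilities Named probabilities over the 27 class labels
#'   (see [enumerate_class_space()]); must sum to 1.
#' @param ratio_ranges Named list of `(low, high)` pos/neg ratio intervals
#'   per trinary state; `up` must lie in `[2, Inf)`, `unchanged` in
#'   `[1, 2)`, `down` in `[0, 1)`.
#' @param baseline_log_mean,baseline_log_sd Log-scale mean/sd of the
#'   negative-population FPKM baseline.
#' @param replicate_log_sd Log-scale sd of multiplicative replicate noise.
#' @param pseudocount Pseudocount on which ratios are planted; keep equal
#'   to the one used downstream.
#' @param p_ac_given_increasing,p_ac_given_other Probability that a gene
#'   carries H3K27ac at its TSS in all three positive-population stages,
#'   for genes whose noise-free expression rises strictly across the
#'   stages versus all other genes. The gap between the two plants the
#'   positive association between promoter H3K27ac and rising expression
#'   that the chromatin stage tests for; the defaults keep the overall
#'   consistently-bound fraction near its unconditional value.
#' @param state_probs_pos,state_probs_neg Priors over TSS chromatin states
#'   `(active, repressed, poised, none)` for the two populations; defaults
#'   are the fractions reported for differentiating neurons (72.4% / 0.5%
#'   / 16.4% / 10.7%) and progenitors (0.9% / 4.5% / 58.3% / 36.3%).
#' @param consistency Probability that a gene keeps one chromatin state
#'   across all three positive-population stages (else drawn per stage).
#' @param distal_probs Named per-mark probability that a gene carries a
#'   distal (within 100 kb, outside the TSS window) peak in a sample.
#' @return A named list of parameters for [simulate_bulk()].
#' @export
bulk_sim_params <- function(n_replicates = 2L,
                            class_probabilities = default_class_probabilities(),
                            ratio_ranges = list(up = c(2.2, 6),
                                                unchanged = c(1.05, 1.9),
                                                down = c(0.1, 0.85)),
                            baseline_log_mean = log(20),
                            baseline_log_sd = 1,
                            replicate_log_sd = 0.15,
                            pseudocount = 0.1,
                            p_ac_given_increasing = 0.95,
                            p_ac_given_other = 0.80,
                            state_probs_pos = c(active = 0.724, repressed = 0.005,
                                                poised = 0.164, none = 0.107),
                            state_probs_neg = c(active = 0.009, repressed = 0.045,
                                                poised = 0.583, none = 0.363),
                            distal_probs = c(H3K27ac = 0.465, H3K27me3 = 0.55)) {
  p <- list(
    n_replicates = as.integer(n_replicates),
    class_probabilities = class_probabilities,
    ratio_ranges = ratio_ranges,
    baseline_log_mean = baseline_log_mean,
    baseline_log_sd = baseline_log_sd,
    replicate_log_sd = replicate_log_sd,
    pseudocount = pseudocount,
    p_ac_given_increasing = p_ac_given_increasing,
    p_ac_given_other = p_ac_given_other,
    state_probs_pos = state_probs_pos / sum(state_probs_pos),
    state_probs_neg = state_probs_neg / sum(state_probs_neg),
    distal_probs = distal_probs
  )
  validate_bulk_sim_params(p)
}

validate_bulk_sim_params <- function(p) {
  if (abs(sum(p$class_probabilities) - 1) > 1e-8) {
    abort("class_probabilities must sum to 1.")
  }
  if (!setequal(names(p$class_probabilities), enumerate_class_space()$class)) {
    abort("class_probabilities must be named by the 27 class labels.")
  }
  rr <- p$ratio_ranges
  ok <- rr$up[1] >= 2 && rr$up[1] < rr$up[2] &&
    rr$unchanged[1] >= 1 && rr$unchanged[2] < 2 && rr$unchanged[1] < rr$unchanged[2] &&
    rr$down[1] >= 0 && rr$down[2] < 1 && rr$down[1] < rr$down[2]
  if (!ok) abort("ratio_ranges must respect the state boundaries (up within [2,Inf), unchanged within [1,2), down within [0,1)).")
  if (p$baseline_log_sd <= 0 || p$replicate_log_sd < 0) {
    abort("baseline_log_sd must be > 0 and replicate_log_sd >= 0.")
  }
  p
}

#' Default temporal-class prior for the bulk simulator
#'
#' A realistic transcriptome is dominated by genes that do not change
#' between the two populations; consistently enriched (up-up-up) and
#' consistently depleted (down-down-down) programmes are the next largest
#' classes, and the remaining 24 mixed classes share the rest evenly.
#'
#' @return Named numeric vector of length 27 summing to 1.
#' @export
default_class_probabilities <- function() {
  classes <- enumerate_class_space()$class
  p <- setNames(rep(0.5 / 24, 27), classes)
  p[class_label(c("up", "up", "up"))] <- 0.05
  p[class_label(c("down", "down", "down"))] <- 0.05
  p[class_label(c("unchanged", "unchanged", "unchanged"))] <- 0.40
  p / sum(p)
}

#' Simulate a bulk FPKM table with planted ground truth
#'
#' @param params Parameter list from [bulk_sim_params()].
#' @param annotation Annotation tibble (drives gene ids and biotypes).
#' @param seed Integer seed.
#' @return A list with `table` (an expression table with `biotype`,
#'   `de_p`, `de_fdr` and sample FPKM columns) and `truth`, a tibble of
#'   planted labels per gene: temporal `class`, per-stage ratios, stage
#'   means, `de` flag, `cr_specific` and `layer1` flags, the per-condition
#'   chromatin `state_*` columns, per-mark/-condition `distal_*` flags, and
#'   the noise-free trend category.
#' @export
simulate_bulk <- function(params, annotation, seed = 1L) {
  params <- validate_bulk_sim_params(params)
  set.seed(seed)
  n <- nrow(annotation)
  stages <- stage_levels()
  classes <- enumerate_class_space()
  pc <- params$pseudocount

  gene_class <- sample(names(params$class_probabilities), n, replace = TRUE,
                       prob = params$class_probabilities)
  states <- classes$states[match(gene_class, classes$class)]
  state_mat <- do.call(rbind, states)  # n x 3 of "up"/"unchanged"/"down"

  neg_mean <- exp(rnorm(n, params$baseline_log_mean, params$baseline_log_sd))
  ratio <- matrix(NA_real_, n, 3, dimnames = list(NULL, stages))
  for (s in 1:3) {
    rr <- params$ratio_ranges
    lo <- c(up = rr$up[1], unchanged = rr$unchanged[1], down = rr$down[1])[state_mat[, s]]
    hi <- c(up = rr$up[2], unchanged = rr$unchanged[2], down = rr$down[2])[state_mat[, s]]
    ratio[, s] <- runif(n, lo, hi)
  }

  # positive-population mean realises the planted pseudocounted ratio
  pos_mean <- matrix(pmax(0, ratio * (neg_mean + pc) - pc), n, 3,
                     dimnames = list(NULL, stages))
  increasing_nf <- pos_mean[, 1] < pos_mean[, 2] & pos_mean[, 2] < pos_mean[, 3]

  # chromatin truth: one condition per positive stage plus the progenitor
  # (negative) population at E11.5, matching the study design. Consistent
  # promoter H3K27ac is planted preferentially on genes whose noise-free
  # expression rises, which is the association the contingency analysis
  # downstream is meant to detect; within each arm the stage states follow
  # the per-sample priors (restricted to ac-containing states in the
  # consistently-bound arm) so the state marginals stay anchored.
  state_names <- c("active", "repressed", "poised", "none")
  ac_states <- c("active", "poised")
  p_ac <- if_else(increasing_nf, params$p_ac_given_increasing,
                  params$p_ac_given_other)
  consistent_ac <- runif(n) < p_ac
  chrom_state <- matrix(NA_character_, n, 4,
                        dimnames = list(NULL, c(paste0("pos_", stages), "neg_E11.5")))
  prob_ac_only <- params$state_probs_pos[ac_states]
  for (s in 1:3) {
    chrom_state[consistent_ac, s] <- sample(
      ac_states, sum(consistent_ac), replace = TRUE, prob = prob_ac_only)
  }
  # non-consistent genes: mixture of one shared state and per-stage
  # redraws, rejected until at least one stage lacks H3K27ac
  idx <- which(!consistent_ac)
  if (length(idx) > 0L) {
    for (it in 1:100) {
      shared <- sample(state_names, length(idx), replace = TRUE,
                       prob = params$state_probs_pos)
      keep_shared <- runif(length(idx)) < 0.7
      for (s in 1:3) {
        redraw <- sample(state_names, length(idx), replace = TRUE,
                         prob = params$state_probs_pos)
        chrom_state[idx, s] <- if_else(keep_shared, shared, redraw)
      }
      all_ac <- chrom_state[idx, 1] %in% ac_states &
        chrom_state[idx, 2] %in% ac_states & chrom_state[idx, 3] %in% ac_states
      idx <- idx[all_ac]
      if (length(idx) == 0L) break
    }
    # any stragglers lose the mark at one random stage
    if (length(idx) > 0L) {
      chrom_state[cbind(idx, sample(1:3, length(idx), replace = TRUE))] <- "none"
    }
  }
  chrom_state[, 4] <- sample(state_names, n, replace = TRUE, prob = params$state_probs_neg)

  distal <- list()
  for (mk in names(params$distal_probs)) {
    for (cond in colnames(chrom_state)) {
      distal[[paste("distal", mk, cond, sep = "_")]] <-
        runif(n) < params$distal_probs[[mk]]
    }
  }

  # replicate FPKM values: mean x log-normal noise
  tab <- tibble(gene_id = annotation$gene_id, biotype = annotation$biotype)
  for (pop in population_levels()) {
    for (s in 1:3) {
      mu <- if (pop == "pos") pos_mean[, s] else neg_mean
      for (r in seq_len(params$n_replicates)) {
        noise <- if (params$replicate_log_sd > 0) {
          exp(rnorm(n, 0, params$replicate_log_sd))
        } else rep(1, n)
        tab[[make_sample_key(pop, stages[s], r)]] <- mu * noise
      }
    }
  }

  # planted DE flag: at least one stage with a >= 2-fold difference either way
  de <- apply(ratio, 1, function(r) any(r >= 2 | r <= 0.5))
  de_p <- de_fdr <- numeric(n)
  de_p[de] <- runif(sum(de), 0, 0.009)
  de_fdr[de] <- runif(sum(de), de_p[de], 0.049)
  de_p[!de] <- runif(sum(!de), 0.02, 0.97)
  de_fdr[!de] <- runif(sum(!de), pmax(de_p[!de], 0.1), 1)
  tab$de_p <- de_p
  tab$de_fdr <- de_fdr

  # truth flags from the noise-free means (direct arithmetic, not the
  # pipeline's calling functions)
  cr_specific <- rowSums(pos_mean >= 5) == 3L & rowSums(ratio >= 2) == 3L
  layer1 <- cr_specific & neg_mean <= 15
  increasing <- increasing_nf
  low <- rowSums(pos_mean < 1) == 3L
  decreasing <- pos_mean[, 1] > pos_mean[, 2] & pos_mean[, 2] > pos_mean[, 3]
  trend <- dplyr::case_when(
    increasing ~ "increasing",
    low & decreasing ~ "low_decreasing",
    low ~ "low_stable",
    .default = "other"
  )

  truth <- tibble(
    gene_id = annotation$gene_id,
    biotype = annotation$biotype,
    class = gene_class,
    de = de,
    cr_specific = cr_specific,
    layer1 = layer1,
    trend = trend,
    neg_mean = neg_mean
  )
  for (s in 1:3) {
    truth[[paste0("ratio_", stages[s])]] <- ratio[, s]
    truth[[paste0("pos_mean_", stages[s])]] <- pos_mean[, s]
  }
  for (cond in colnames(chrom_state)) {
    truth[[paste0("state_", cond)]] <- chrom_state[, cond]
  }
  for (nm in names(distal)) truth[[nm]] <- distal[[nm]]

  list(table = validate_expression_table(tab), truth = truth)
}
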