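#' Sequence-context mutation-rate model
#'
#' Describes per-site EMS mutation hazards. The hazard at a site is
#' `base_rate` multiplied by `gc_multiplier` when the reference base is G or
#' C, by the matching entry of `kmer_multipliers` when the trinucleotide
#' ending at the site (positions -2/-1/0, site last) matches, and by
#' `heterochromatin_multiplier` when the site lies in a heterochromatin
#' domain. EMS ethylates O6-guanine, so conditional on a G/C site the drawn
#' substitution is a transition (G>A or C>T) with probability
#' `gc_transition_prob`.
#'
#' Defaults encode the biases of a genome-scale rice EMS screen:
#' `base_rate` at the empirical per-bulk scale (~1e-6 mutations/bp/bulk),
#' a strong G/C preference, an AAG trinucleotide context preference, and
#' heterochromatin enrichment.
#'
#' @param base_rate Mutations per bp per bulk at an unmodified site.
#' @param gc_multiplier Fold-increase of the hazard at G/C sites.
#' @param kmer_multipliers Named numeric vector; names are trinucleotides in
#'   the -2/-1/0 frame (mutated site last), values fold-changes.
#' @param heterochromatin_multiplier Fold-increase inside heterochromatin.
#' @param gc_transition_prob P(transition | mutated G/C site).
#' @param at_transition_prob P(transition | mutated A/T site).
#' @return A list of class `context_rate_model`.
#' @export
context_rate_model <- function(base_rate = 1e-6,
                               gc_multiplier = 4,
                               kmer_multipliers = c(AAG = 3),
                               heterochromatin_multiplier = 3,
                               gc_transition_prob = 0.85,
                               at_transition_prob = 0.5) {
  if (base_rate < 0) abort("`base_rate` must be >= 0")
  mult <- c(gc_multiplier, heterochromatin_multiplier, kmer_multipliers)
  if (any(mult <= 0)) abort("rate multipliers must be > 0")
  check_fraction(gc_transition_prob, "gc_transition_prob")
  check_fraction(at_transition_prob, "at_transition_prob")
  if (length(kmer_multipliers) > 0 &&
      (is.null(names(kmer_multipliers)) ||
       any(nchar(names(kmer_multipliers)) != 3))) {
    abort("`kmer_multipliers` must be named by trinucleotides")
  }
  structure(
    list(
      base_rate = base_rate,
      gc_multiplier = gc_multiplier,
      kmer_multipliers = kmer_multipliers,
      heterochromatin_multiplier = heterochromatin_multiplier,
      gc_transition_prob = gc_transition_prob,
      at_transition_prob = at_transition_prob
    ),
    class = "context_rate_model"
  )
}

#' Identity rate model (uniform mutation placement)
#'
#' @param base_rate Mutations per bp per bulk.
#' @return A `context_rate_model` with all multipliers equal to 1.
#' @export
identity_rate_model <- function(base_rate = 1e-6) {
  context_rate_model(
    base_rate = base_rate,
    gc_multiplier = 1,
    kmer_multipliers = numeric(0),
    heterochromatin_multiplier = 1
  )
}

#' Simulation configuration for a pooled-F2 EMS mutagenesis screen
#'
#' The defaults emulate the design of a 52-bulk rice screen: each bulk pools
#' 30 F2 individuals of the mutant phenotype resequenced to ~39x depth, so
#' the expected alt-read fraction (SNP index) is 0.5 at unlinked
#' heterozygous EMS sites and 1.0 at the causal site. Shared natural
#' variants, sequencing-error sites, and residual heterozygous fragments
#' are overlaid as in real bulk data.
#'
#' @param seed Integer seed; fixes all downstream randomness.
#' @param n_chrom Number of chromosomes.
#' @param chrom_len Chromosome length(s) in bp (recycled to `n_chrom`).
#' @param n_bulks Number of mutant bulks.
#' @param pool_size Individuals pooled per bulk.
#' @param depth Mean sequencing depth per site.
#' @param seq_error_rate Maximum alt-read fraction at sequencing-error sites.
#' @param error_site_rate Error sites per bp per bulk appearing in the raw
#'   variant table.
#' @param natural_site_rate Shared (background) homozygous variant sites per
#'   bp; these appear in every bulk.
#' @param residual_fragment_prob Probability that a bulk carries one residual
#'   heterozygous fragment.
#' @param residual_fragment_len Length of such a fragment in bp.
#' @param residual_fragment_density Heterozygous-site density inside a
#'   residual fragment (sites per bp).
#' @param het_fraction Fraction of each chromosome that is (centromeric)
#'   heterochromatin; the remainder is euchromatin split across both arms.
#' @param gc_eu,gc_het Realized GC composition targets per domain kind
#'   (island and depletion effects are compensated internally).
#' @param cpg_depletion Probability that the G of a background CpG
#'   dinucleotide is resampled to A/T (methylation-driven CpG decay outside
#'   islands; plant genomes are CpG-depleted genome-wide).
#' @param cpg_island_rate_eu,cpg_island_rate_het Planted CpG islands per bp
#'   per domain kind (denser in heterochromatin).
#' @param cpg_island_len Island length range (bp).
#' @param cpg_island_gc GC composition of planted islands (no depletion, so
#'   observed/expected CpG inside them is ~1).
#' @param ems_rate_model A [context_rate_model()].
#' @param n_varieties Varieties in the natural-SNP panel.
#' @param panel_site_rate Panel sites per bp.
#' @param panel_overlap_fraction Fraction of panel sites placed at implanted
#'   EMS positions (drives the sharing analysis).
#' @param n_expr_datasets Expression datasets (columns of the FPKM matrix).
#' @param n_genes Gene models to place.
#' @param te_fraction Fraction of genes annotated as TE genes.
#' @param te_het_weight Placement weight of TE genes in heterochromatin
#'   relative to euchromatin.
#' @param mq20_pass Probability that an alt read passes mapping quality >= 20.
#' @param dh_rate_eu,dh_rate_het DNase I hypersensitive sites per bp.
#' @param signal_contrast Fold-contrast of domain-biased signal-track means.
#' @param n_experiments Named integer vector: experiments per modification.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_chrom = 1L,
                       chrom_len = 5e6,
                       n_bulks = 52L,
                       pool_size = 30L,
                       depth = 39,
                       seq_error_rate = 0.02,
                       error_site_rate = 1e-5,
                       natural_site_rate = 2e-4,
                       residual_fragment_prob = 0.2,
                       residual_fragment_len = 150000,
                       residual_fragment_density = 8e-4,
                       het_fraction = 0.4,
                       gc_eu = 0.40,
                       gc_het = 0.55,
                       cpg_depletion = 0.7,
                       cpg_island_rate_eu = 1 / 6000,
                       cpg_island_rate_het = 1 / 2500,
                       cpg_island_len = c(300, 800),
                       cpg_island_gc = 0.65,
                       ems_rate_model = context_rate_model(),
                       n_varieties = 40L,
                       panel_site_rate = 1e-4,
                       panel_overlap_fraction = 0.2,
                       n_expr_datasets = 284L,
                       n_genes = 200L,
                       te_fraction = 0.3,
                       te_het_weight = 5,
                       mq20_pass = 0.95,
                       dh_rate_eu = 4e-4,
                       dh_rate_het = 1e-4,
                       signal_contrast = 3,
                       n_experiments = c(
                         DNA_methylation = 3L, MNase = 2L,
                         H3K9ac = 3L, H2A.Z = 2L
                       )) {
  if (n_chrom < 1) abort("`n_chrom` must be >= 1")
  chrom_len <- rep_len(chrom_len, n_chrom)
  if (any(chrom_len <= 0)) abort("chromosome lengths must be positive")
  if (n_bulks < 1) abort("`n_bulks` must be >= 1")
  if (n_varieties < 2) abort("`n_varieties` must be >= 2")
  check_fraction(seq_error_rate, "seq_error_rate")
  check_fraction(het_fraction, "het_fraction")
  check_fraction(gc_eu, "gc_eu")
  check_fraction(gc_het, "gc_het")
  check_fraction(cpg_depletion, "cpg_depletion")
  check_fraction(cpg_island_gc, "cpg_island_gc")
  check_fraction(mq20_pass, "mq20_pass")
  stopifnot(inherits(ems_rate_model, "context_rate_model"))
  structure(
    list(
      seed = as.integer(seed), n_chrom = as.integer(n_chrom),
      chrom_len = chrom_len, n_bulks = as.integer(n_bulks),
      pool_size = as.integer(pool_size), depth = depth,
      seq_error_rate = seq_error_rate, error_site_rate = error_site_rate,
      natural_site_rate = natural_site_rate,
      residual_fragment_prob = residual_fragment_prob,
      residual_fragment_len = residual_fragment_len,
      residual_fragment_density = residual_fragment_density,
      het_fraction = het_fraction, gc_eu = gc_eu, gc_het = gc_het,
      cpg_depletion = cpg_depletion,
      cpg_island_rate_eu = cpg_island_rate_eu,
      cpg_island_rate_het = cpg_island_rate_het,
      cpg_island_len = cpg_island_len, cpg_island_gc = cpg_island_gc,
      ems_rate_model = ems_rate_model,
      n_varieties = as.integer(n_varieties),
      panel_site_rate = panel_site_rate,
      panel_overlap_fraction = panel_overlap_fraction,
      n_expr_datasets = as.integer(n_expr_datasets),
      n_genes = as.integer(n_genes), te_fraction = te_fraction,
      te_het_weight = te_het_weight, mq20_pass = mq20_pass,
      dh_rate_eu = dh_rate_eu, dh_rate_het = dh_rate_het,
      signal_contrast = signal_contrast, n_experiments = n_experiments
    ),
    class = "sim_config"
  )
}
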