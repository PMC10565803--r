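# Shared fixtures built in code.

# Minimal well-formed summary-statistic data.frame.
make_sumstats <- function(snp_id = c("rs1", "rs2", "rs3"),
                          chrom = c("1", "1", "2"),
                          pos = c(1000L, 2000L, 3000L),
                          effect_allele = c("A", "C", "G"),
                          other_allele = c("G", "T", "A"),
                          eaf = c(0.2, 0.3, 0.4),
                          beta = c(0.1, -0.2, 0.05),
                          se = c(0.02, 0.03, 0.04),
                          pvalue = c(1e-7, 1e-9, 0.2),
                          n = c(18340, 18340, 18340)) {
  data.frame(snp_id = snp_id, chrom = chrom, pos = pos,
             effect_allele = effect_allele, other_allele = other_allele,
             eaf = eaf, beta = beta, se = se, pvalue = pvalue, n = n,
             stringsAsFactors = FALSE)
}

make_dataset <- function(..., trait_id = "genus.TestTaxon",
                         trait_type = "exposure") {
  gwas_dataset(make_sumstats(...), trait_id, trait_type, quiet = TRUE)
}

# Harmonized set from a simulated taxon: select suggestive SNPs and align.
sim_harmonized <- function(truth, trait_id = "genus.SimTaxon") {
  sim <- simulate_taxon(truth, trait_id)
  instruments <- filter_by_pvalue(sim$exposure, 1e-5)
  list(h = harmonize(instruments, sim$outcome), sim = sim)
}

# Build a multi-taxon batch on one shared outcome panel: each taxon's SNPs
# get a unique prefix, outcome rows are pooled, LD is identity (independent
# SNPs, consistent with the generator's spaced positions).
make_batch <- function(truths, trait_ids) {
  stopifnot(length(truths) == length(trait_ids))
  exposures <- vector("list", length(truths))
  outcome_rows <- vector("list", length(truths))
  for (i in seq_along(truths)) {
    sim <- simulate_taxon(truths[[i]], trait_ids[i])
    prefix <- sprintf("t%03d_", i)
    exp_df <- as.data.frame(sim$exposure)
    out_df <- as.data.frame(sim$outcome)
    exp_df$snp_id <- paste0(prefix, exp_df$snp_id)
    out_df$snp_id <- paste0(prefix, out_df$snp_id)
    exposures[[i]] <- gwas_dataset(exp_df, trait_ids[i], "exposure",
                                   quiet = TRUE)
    outcome_rows[[i]] <- out_df
  }
  out_all <- do.call(rbind, outcome_rows)
  ids <- out_all$snp_id
  list(exposures = exposures,
       outcome = gwas_dataset(out_all, "outcome", "outcome", quiet = TRUE),
       ld = ld_matrix(diag(length(ids)), ids))
}

# Exhaustive pairwise check of the clumping contract: no retained pair may be
# simultaneously on one chromosome within the window and above the r2
# threshold; every removed candidate must violate the rule with some retained
# SNP of better (or tie-broken-better) rank.
check_clump_contract <- function(input, retained, ld, config) {
  in_df <- as.data.frame(input)
  kept <- retained$snp_id
  removed <- setdiff(in_df$snp_id, kept)
  row_of <- function(id) in_df[in_df$snp_id == id, ]
  violates <- function(a, b) {
    ra <- row_of(a); rb <- row_of(b)
    ra$chrom == rb$chrom &&
      abs(ra$pos - rb$pos) <= config$window_kb * 1000 &&
      ld[a, b] > config$r2_threshold
  }
  better <- function(a, b) {
    ra <- row_of(a); rb <- row_of(b)
    for (key in list(c(ra$pvalue, rb$pvalue), c(ra$chrom, rb$chrom),
                     c(ra$pos, rb$pos), c(ra$snp_id, rb$snp_id))) {
      if (key[1] < key[2]) return(TRUE)
      if (key[1] > key[2]) return(FALSE)
    }
    FALSE
  }
  pair_ok <- TRUE
  if (length(kept) > 1) {
    for (i in seq_along(kept)[-1]) {
      for (j in seq_len(i - 1)) {
        if (violates(kept[i], kept[j])) pair_ok <- FALSE
      }
    }
  }
  removed_ok <- all(vapply(removed, function(id) {
    any(vapply(kept, function(k) better(k, id) && violates(k, id), logical(1)))
  }, logical(1)))
  list(pair_ok = pair_ok, removed_ok = removed_ok)
}
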