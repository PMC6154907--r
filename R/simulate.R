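# Synthetic contig generator: multi-experiment datasets of contigs with
# planted ORFs whose synonymous-codon choice differs between the virus and
# non-virus classes on a small set of codons, plus per-experiment batch
# effects and optional indel noise. Only codon *choice* carries class signal
# (amino-acid composition is uniform over the 18 multi-codon amino acids), so
# downstream classification accuracy is attributable to RSCU alone.

# default planted codons and their host/virus RSCU calibration at
# divergence 1; TCG and CGC use the observed metagenomic class means
# (non-viral 0.39/0.53, viral 0.60/0.80), the remaining four follow the same
# low-in-host / higher-in-virus pattern.
.default_skew_targets <- function() {
  tibble(
    codon = c("TCG", "CGC", "CGA", "GCG", "GTA", "CCG"),
    host_rscu = c(0.39, 0.53, 0.42, 0.40, 0.52, 0.42),
    virus_rscu = c(0.60, 0.80, 0.74, 0.72, 0.90, 0.76)
  )
}

#' Default planted codons of the synthetic generator
#'
#' The six codons whose usage differs between the synthetic virus and host
#' classes: TCG (Ser), CGC and CGA (Arg), GCG (Ala), GTA (Val), CCG (Pro).
#'
#' @return Character vector of six codons.
#' @export
default_skewed_codons <- function() .default_skew_targets()$codon

# expand per-codon RSCU targets into within-family codon probabilities:
# RSCU r in a family of size n corresponds to probability r / n; the family's
# remaining mass is shared uniformly by its non-skewed codons.
.profile_from_targets <- function(targets) {
  ct <- codon_table()
  sense <- ct[ct$amino_acid != "*", ]
  probs <- numeric(nrow(sense))
  names(probs) <- sense$codon
  for (aa in unique(sense$amino_acid)) {
    fam <- sense$codon[sense$amino_acid == aa]
    n <- length(fam)
    skewed <- intersect(fam, targets$codon)
    p <- rep(1 / n, n)
    names(p) <- fam
    if (length(skewed) > 0L) {
      p[skewed] <- targets$rscu[match(skewed, targets$codon)] / n
      rest <- setdiff(fam, skewed)
      remaining <- 1 - sum(p[skewed])
      if (remaining <= 0) {
        abort(sprintf("skewed-codon targets in family %s leave no probability mass", aa))
      }
      p[rest] <- remaining / length(rest)
    }
    probs[fam] <- p
  }
  tibble(
    codon = sense$codon,
    amino_acid = sense$amino_acid,
    family_size = sense$family_size,
    prob = unname(probs)
  )
}

#' Build host and virus codon-usage profiles with a planted divergence
#'
#' Each profile gives, per amino acid, a probability distribution over its
#' synonymous codons. The host profile is uniform except on the skewed
#' codons, whose expected RSCU is pulled below 1; the virus profile pushes
#' the same codons above the host level. `divergence` linearly interpolates
#' both profiles between uniform usage (divergence 0: the two profiles are
#' identical) and the full calibration targets (divergence 1: TCG expected
#' RSCU 0.39 in host vs 0.60 in virus, CGC 0.53 vs 0.80, and analogous
#' values for the other planted codons).
#'
#' @param divergence Non-negative scale of the planted deviation (default 1,
#'   the calibrated level).
#' @param skewed_codons Codons carrying the class signal (default
#'   [default_skewed_codons()]); must be valid non-stop codons.
#' @param targets Optional tibble `codon`, `host_rscu`, `virus_rscu`
#'   overriding the divergence-1 calibration for `skewed_codons`.
#' @return A list with elements `host` and `virus`, each a tibble `codon`,
#'   `amino_acid`, `family_size`, `prob` over the 61 sense codons
#'   (probabilities sum to 1 within each amino-acid family).
#' @export
make_class_profiles <- function(divergence = 1, skewed_codons = default_skewed_codons(),
                                targets = NULL) {
  stopifnot(divergence >= 0)
  ct <- codon_table()
  bad <- !(skewed_codons %in% ct$codon[ct$amino_acid != "*"])
  if (any(bad)) {
    abort(sprintf("invalid or stop codon in skewed_codons: %s", skewed_codons[bad][1]))
  }
  if (is.null(targets)) {
    defaults <- .default_skew_targets()
    targets <- tibble(
      codon = skewed_codons,
      host_rscu = ifelse(skewed_codons %in% defaults$codon,
        defaults$host_rscu[match(skewed_codons, defaults$codon)], 0.45
      ),
      virus_rscu = ifelse(skewed_codons %in% defaults$codon,
        defaults$virus_rscu[match(skewed_codons, defaults$codon)], 0.72
      )
    )
  }
  host_t <- tibble(codon = targets$codon, rscu = 1 + divergence * (targets$host_rscu - 1))
  virus_t <- tibble(codon = targets$codon, rscu = 1 + divergence * (targets$virus_rscu - 1))
  list(
    host = .profile_from_targets(host_t),
    virus = .profile_from_targets(virus_t)
  )
}

# Codon sampling distribution implied by a profile: amino acids uniform over
# the 18 multi-codon families, codon within a family per the profile. Met and
# Trp are excluded (their single codons carry no synonymous-usage signal and
# ATG would open spurious reading frames inside ORFs anyway -- start codons
# are planted explicitly).
.codon_sampler <- function(profile) {
  multi <- profile[profile$family_size > 1L, ]
  prob <- multi$prob / length(unique(multi$amino_acid))
  list(codons = multi$codon, prob = prob / sum(prob))
}

# Frame-breaker codon run inserted periodically inside planted ORFs. In frame
# 0 it reads Leu-Ile-Asn-Tyr (CTA ATT AAC TAC), sense codons from families
# that never carry planted signal; its internal junctions spell stop codons in
# both shifted forward frames, and its reverse complement (GTAGTTAATTAG)
# contains stops in all three reverse frames. This keeps spurious
# out-of-frame ORFs from reaching the minimum length, so counted codons come
# from the planted frame and strand.
.frame_breaker <- "CTAATTAACTAC"

# Intergenic spacer with stop codons in all frames of both strands, so no ORF
# can span it: TAATAATAA stops all forward frames, TTATTATTA all reverse ones.
.spacer <- function() {
  filler <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
  paste0("TAATAATAA", filler(sample(6:18, 1L)), "TTATTATTA", filler(sample(6:18, 1L)))
}

.apply_indels <- function(sequence, rate) {
  if (rate <= 0) {
    return(sequence)
  }
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  hit <- runif(length(chars)) < rate
  if (!any(hit)) {
    return(sequence)
  }
  out <- chars
  for (i in which(hit)) {
    if (runif(1) < 0.5) {
      out[i] <- "" # deletion
    } else {
      out[i] <- paste0(out[i], sample(c("A", "C", "G", "T"), 1L)) # insertion
    }
  }
  paste(out, collapse = "")
}

#' Generate one synthetic contig
#'
#' Builds `n_orfs` planted ORFs -- each `ATG`, then codons drawn from the
#' class profile (amino acids uniform over the 18 multi-codon amino acids,
#' codon within the family per the profile), then a stop codon -- separated by
#' intergenic spacers that contain stop codons in every frame of both strands,
#' so the background hosts no long spurious ORFs. Optional uniform indel noise
#' emulates assembly frameshifts. Uses the current RNG state; seed via the
#' caller (e.g. [generate_dataset()]).
#'
#' @param profile Profile tibble (one element of [make_class_profiles()]).
#' @param contig_length Approximate target length in nt.
#' @param n_orfs Number of planted ORFs.
#' @param indel_rate Per-nucleotide indel probability (default 0).
#' @param min_orf_codons Minimum codons per planted ORF including the start
#'   codon (default 42, i.e. 126 coding nt).
#' @return A single DNA string.
#' @export
generate_contig <- function(profile, contig_length, n_orfs, indel_rate = 0,
                            min_orf_codons = 42L) {
  n_orfs <- .assert_scalar_int(n_orfs, "n_orfs")
  sampler <- .codon_sampler(profile)
  spacers <- replicate(n_orfs + 1L, .spacer())
  budget <- contig_length - sum(nchar(spacers)) - 3L * n_orfs # minus stop codons
  if (budget < n_orfs * 3L * min_orf_codons) {
    abort(sprintf(
      "contig_length %d is too short to host %d ORFs of >= %d codons",
      contig_length, n_orfs, min_orf_codons
    ))
  }
  # split the coding budget unevenly but keep every ORF above the minimum
  w <- runif(n_orfs, 0.8, 1.2)
  orf_codons <- pmax(min_orf_codons, floor(budget / 3L * w / sum(w)))
  orfs <- vapply(orf_codons, function(k) {
    body <- sample(sampler$codons, k - 1L, replace = TRUE, prob = sampler$prob)
    # splice a frame-breaker run in every ~25 codons so no shifted-frame ORF
    # can reach the reporting length
    chunks <- split(body, ceiling(seq_along(body) / 25L))
    coding <- paste(vapply(chunks, paste, character(1), collapse = ""),
      collapse = .frame_breaker
    )
    paste0("ATG", coding, sample(.stop_codons(), 1L))
  }, character(1))
  seq_ <- paste0(paste0(spacers[seq_len(n_orfs)], orfs, collapse = ""), spacers[n_orfs + 1L])
  .apply_indels(seq_, indel_rate)
}

# per-experiment batch perturbation of a profile: logit-normal jitter of the
# within-family codon probabilities, renormalized per family
.perturb_profile <- function(profile, shift) {
  q <- stats::plogis(stats::qlogis(pmin(pmax(profile$prob, 1e-6), 1 - 1e-6)) + shift)
  for (aa in unique(profile$amino_acid)) {
    rows <- profile$amino_acid == aa
    profile$prob[rows] <- q[rows] / sum(q[rows])
  }
  profile
}

#' Generate a labeled multi-experiment contig dataset
#'
#' Emulates the data regime of a multi-run viral metagenomics study: several
#' sequencing experiments of assembled contigs, a rare virus class (default
#' prevalence 3%), planted codon-usage divergence between the classes, and a
#' per-experiment batch effect (a shared logit-normal shift of the codon
#' probabilities of both class profiles) so that generalization across
#' experiments is genuinely harder than within-experiment splits. Fully
#' reproducible from `seed`.
#'
#' @param n_experiments Number of experiments (default 10).
#' @param contigs_per_experiment Contigs per experiment (default 200).
#' @param virus_prevalence Probability a contig is viral (default 0.03).
#' @param contig_length Length range in nt to sample from (default
#'   `c(1200, 4000)`).
#' @param orfs_per_contig Range of planted ORFs per contig (default
#'   `c(2, 5)`).
#' @param divergence Planted class divergence passed to
#'   [make_class_profiles()] (default 1, the calibrated level).
#' @param skewed_codons Planted codons (default [default_skewed_codons()]).
#' @param batch_effect_sd Standard deviation of the per-experiment
#'   logit-scale codon-probability shift (default 0.10).
#' @param indel_noise_rate Per-nucleotide indel probability (default 0).
#' @param seed Integer seed.
#' @return A contig tibble (`id`, `sequence`, `experiment_id`, `label`) with
#'   experiment IDs `e00`, `e01`, ... and the generator configuration stored
#'   in `attr(, "config")`.
#' @export
generate_dataset <- function(n_experiments = 10L, contigs_per_experiment = 200L,
                             virus_prevalence = 0.03,
                             contig_length = c(1200L, 4000L),
                             orfs_per_contig = c(2L, 5L),
                             divergence = 1,
                             skewed_codons = default_skewed_codons(),
                             batch_effect_sd = 0.10,
                             indel_noise_rate = 0,
                             seed = 1L) {
  stopifnot(
    virus_prevalence > 0, virus_prevalence < 1,
    length(contig_length) == 2L, contig_length[1] <= contig_length[2],
    length(orfs_per_contig) == 2L, orfs_per_contig[1] >= 1L,
    batch_effect_sd >= 0, indel_noise_rate >= 0
  )
  n_experiments <- .assert_scalar_int(n_experiments, "n_experiments")
  contigs_per_experiment <- .assert_scalar_int(contigs_per_experiment, "contigs_per_experiment")
  profiles <- make_class_profiles(divergence, skewed_codons)
  config <- list(
    n_experiments = n_experiments, contigs_per_experiment = contigs_per_experiment,
    virus_prevalence = virus_prevalence, contig_length = as.integer(contig_length),
    orfs_per_contig = as.integer(orfs_per_contig), divergence = divergence,
    skewed_codons = skewed_codons, batch_effect_sd = batch_effect_sd,
    indel_noise_rate = indel_noise_rate, seed = as.integer(seed)
  )
  out <- .with_seed(seed, {
    experiments <- vector("list", n_experiments)
    for (e in seq_len(n_experiments)) {
      exp_id <- sprintf("e%02d", e - 1L)
      shift <- rnorm(nrow(profiles$host), sd = batch_effect_sd)
      host_e <- .perturb_profile(profiles$host, shift)
      virus_e <- .perturb_profile(profiles$virus, shift)
      labels <- ifelse(runif(contigs_per_experiment) < virus_prevalence, "virus", "non_virus")
      lengths <- sample(contig_length[1]:contig_length[2], contigs_per_experiment, replace = TRUE)
      n_orfs <- sample(orfs_per_contig[1]:orfs_per_contig[2], contigs_per_experiment, replace = TRUE)
      # a short contig cannot host many ORFs plus spacers; clamp the draw
      n_orfs <- pmin(n_orfs, pmax(orfs_per_contig[1], (lengths - 60L) %/% 210L))
      seqs <- character(contigs_per_experiment)
      for (i in seq_len(contigs_per_experiment)) {
        prof <- if (labels[i] == "virus") virus_e else host_e
        seqs[i] <- generate_contig(prof, lengths[i], n_orfs[i], indel_noise_rate)
      }
      experiments[[e]] <- tibble(
        id = sprintf("%s_c%04d", exp_id, seq_len(contigs_per_experiment) - 1L),
        sequence = seqs,
        experiment_id = exp_id,
        label = labels
      )
    }
    bind_rows(experiments)
  })
  attr(out, "config") <- config
  out
}
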