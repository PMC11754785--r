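.aa_no_kr <- strsplit("ACDEFGHILMNPQSTVWY", "")[[1L]]

#' Parameters for the synthetic DIA experiment generator
#'
#' Defaults encode the desk-scale study conditions the package is validated
#' under: a 200-protein proteome in which photosynthesis-associated lumenal
#' proteins are depleted by 1 log2 unit in the affected condition while 20
#' planted "accumulator" proteins additionally gain +3 log2 on their
#' targeting-region peptides, with four replicates per condition and 0.25
#' log2 replicate noise (calibrated to the printed ratio ranges of the
#' ratio-gap selection, roughly -1.5 to +4.1 log2).
#'
#' @param n_proteins number of simulated proteins.
#' @param class_fractions named proportions over classes `photosynthesis`
#'   (thylakoid-lumen proteins carrying bipartite cTP+lTP presequences),
#'   `chloroplast_other` (stromal, cTP only) and `background` (no targeting
#'   sequence); must sum to 1.
#' @param n_replicates replicates per condition.
#' @param base_log2_mean,between_protein_sd log2 location and spread of
#'   protein base abundance.
#' @param peptide_offset_sd sd of the fixed per-peptide ionization offset
#'   (log2); drawn once per peptide so it cancels from ratios.
#' @param noise_sd replicate-level log2 noise; 0 gives the exact zero-noise
#'   limit.
#' @param protein_effect_log2 named list: condition -> named numeric vector
#'   of log2 effects per class. The first condition is the reference.
#' @param n_accumulators,preprotein_set planted preprotein accumulators;
#'   `preprotein_set` (ids) overrides `n_accumulators` and must be a subset
#'   of the lumenal photosynthesis proteins.
#' @param preprotein_condition condition in which targeting-region peptides
#'   of accumulators gain `preprotein_peptide_effect_log2`.
#' @param preprotein_peptide_effect_log2 planted log2 gain on
#'   targeting-region peptides of accumulators.
#' @param targeting_baseline_log2 log2 offset of targeting-region peptide
#'   baseline abundance relative to mature peptides. Preproteins are a
#'   minority species (a few percent) in controls, so targeting-spanning
#'   peptides sit near the detection limit; without this offset the planted
#'   gain would inflate the parent protein sum and mask its depletion.
#' @param mnar_quantile,dropout_prob missing-not-at-random model: cells whose
#'   latent log2 intensity falls in the lowest `mnar_quantile` of all values
#'   are set missing with probability `dropout_prob`.
#' @param min_len,max_len,max_missed tryptic digestion bounds (residues /
#'   missed cleavage sites).
#' @param seed integer seed; the whole simulation is a deterministic
#'   function of the parameters.
#' @return A list of class `simulation_params`.
#' @export
simulation_params <- function(n_proteins = 200L,
                              class_fractions = c(photosynthesis = 0.15,
                                                  chloroplast_other = 0.25,
                                                  background = 0.60),
                              n_replicates = 4L,
                              base_log2_mean = 20,
                              between_protein_sd = 2,
                              peptide_offset_sd = 1,
                              noise_sd = 0.25,
                              protein_effect_log2 = list(
                                Col_RL = c(photosynthesis = 0,
                                           chloroplast_other = 0,
                                           background = 0),
                                abc1k1_RL = c(photosynthesis = -1,
                                              chloroplast_other = -0.15,
                                              background = 0)),
                              n_accumulators = 20L,
                              preprotein_set = NULL,
                              preprotein_condition = "abc1k1_RL",
                              preprotein_peptide_effect_log2 = 3,
                              targeting_baseline_log2 = -5,
                              mnar_quantile = 0.10,
                              dropout_prob = 0.5,
                              min_len = 7L, max_len = 52L, max_missed = 2L,
                              seed = 1L) {
  classes <- c("photosynthesis", "chloroplast_other", "background")
  if (!setequal(names(class_fractions), classes)) {
    stop("class_fractions must be named with: ", paste(classes, collapse = ", "))
  }
  if (abs(sum(class_fractions) - 1) > 1e-9) {
    stop("class_fractions must sum to 1")
  }
  if (n_proteins < 1L) stop("n_proteins must be >= 1")
  if (between_protein_sd <= 0 || peptide_offset_sd <= 0) {
    stop("abundance spread sds must be > 0")
  }
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (max_len < min_len) stop("max_len < min_len: infeasible digestion bounds")
  if (mnar_quantile < 0 || mnar_quantile > 1 ||
      dropout_prob < 0 || dropout_prob > 1) {
    stop("mnar_quantile and dropout_prob must be proportions in [0, 1]")
  }
  for (cond in names(protein_effect_log2)) {
    missing_cls <- setdiff(classes, names(protein_effect_log2[[cond]]))
    if (length(missing_cls) > 0L) {
      stop("protein_effect_log2[['", cond, "']] lacks class(es): ",
           paste(missing_cls, collapse = ", "))
    }
  }
  if (!(preprotein_condition %in% names(protein_effect_log2))) {
    stop("preprotein_condition '", preprotein_condition,
         "' not among simulated conditions")
  }
  structure(
    list(n_proteins = as.integer(n_proteins),
         class_fractions = class_fractions[classes],
         n_replicates = as.integer(n_replicates),
         base_log2_mean = base_log2_mean,
         between_protein_sd = between_protein_sd,
         peptide_offset_sd = peptide_offset_sd,
         noise_sd = noise_sd,
         protein_effect_log2 = protein_effect_log2,
         n_accumulators = as.integer(n_accumulators),
         preprotein_set = preprotein_set,
         preprotein_condition = preprotein_condition,
         preprotein_peptide_effect_log2 = preprotein_peptide_effect_log2,
         targeting_baseline_log2 = targeting_baseline_log2,
         mnar_quantile = mnar_quantile,
         dropout_prob = dropout_prob,
         min_len = as.integer(min_len), max_len = as.integer(max_len),
         max_missed = as.integer(max_missed),
         seed = as.integer(seed)),
    class = "simulation_params"
  )
}

#' In-silico tryptic digestion (Trypsin/P)
#'
#' Cleaves after every K or R with no proline exception and enumerates all
#' contiguous fragments with at most `max_missed` internal cleavage sites,
#' keeping those with length in `[min_len, max_len]`. Positions are 1-based,
#' inclusive, in the input sequence.
#'
#' @param sequence amino-acid string.
#' @param min_len,max_len fragment length bounds (residues).
#' @param max_missed maximum internal missed cleavage sites.
#' @return data.frame with columns `sequence`, `start`, `end`, `missed`.
#' @export
digest_protein <- function(sequence, min_len = 7L, max_len = 52L,
                           max_missed = 2L) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  if (max_len < min_len) stop("max_len < min_len: infeasible digestion bounds")
  if (max_missed < 0L) stop("max_missed must be >= 0")
  n <- nchar(sequence)
  chars <- strsplit(toupper(sequence), "")[[1L]]
  sites <- which(chars %in% c("K", "R"))
  bounds <- unique(c(0L, sites, n))
  nb <- length(bounds)
  starts <- integer(0); ends <- integer(0); missed <- integer(0)
  for (i in seq_len(nb - 1L)) {
    j_max <- min(i + 1L + max_missed, nb)
    for (j in (i + 1L):j_max) {
      starts <- c(starts, bounds[i] + 1L)
      ends <- c(ends, bounds[j])
      missed <- c(missed, j - i - 1L)
    }
  }
  len <- ends - starts + 1L
  keep <- len >= min_len & len <= max_len
  data.frame(
    sequence = substring(sequence, starts[keep], ends[keep]),
    start = starts[keep], end = ends[keep], missed = missed[keep],
    stringsAsFactors = FALSE
  )
}

.digest_proteome <- function(proteins, params) {
  frags <- lapply(names(proteins), function(id) {
    d <- digest_protein(proteins[[id]], params$min_len, params$max_len,
                        params$max_missed)
    if (nrow(d) == 0L) return(NULL)
    data.frame(
      peptide_id = sprintf("%s_%d_%d", id, d$start, d$end),
      sequence = d$sequence, parent = id, start = d$start, end = d$end,
      proteotypic = TRUE, stringsAsFactors = FALSE
    )
  })
  do.call(rbind, frags)
}

.random_protein_sequence <- function(target_len) {
  segs <- character(0)
  total <- 0L
  while (total < target_len) {
    seg_len <- sample(7:24, 1L)
    if (target_len - (total + seg_len) < 7L) seg_len <- target_len - total
    body_len <- max(seg_len - 1L, 0L)
    seg <- paste(c(sample(.aa_no_kr, body_len, replace = TRUE),
                   if (total + seg_len < target_len) sample(c("K", "R"), 1L)
                   else sample(.aa_no_kr, 1L)),
                 collapse = "")
    segs <- c(segs, seg)
    total <- total + seg_len
  }
  paste(segs, collapse = "")
}

#' Generate a synthetic proteome with targeting-sequence annotations
#'
#' Sequences are built from tryptic segments (each ending in K or R) so
#' every protein yields several quantifiable peptides in the digestion
#' window. Photosynthesis-class proteins are thylakoid-lumen residents with
#' a bipartite presequence (`ctp_end` in 25-60, `ltp_end` 15-45 residues
#' further); other chloroplast proteins are stromal with a cTP only;
#' background proteins carry no targeting sequence.
#'
#' @param params [simulation_params()].
#' @return List with `proteins` (named sequences), `annotations`
#'   (see [read_annotations()]) and `classes` (protein_id, class).
#' @export
generate_proteome <- function(params) {
  stopifnot(inherits(params, "simulation_params"))
  withr::with_seed(params$seed, {
    n <- params$n_proteins
    counts <- floor(params$class_fractions * n)
    counts[1L] <- counts[1L] + (n - sum(counts))
    class <- rep(names(counts), counts)
    ids <- sprintf("PROT%04d", seq_len(n))
    lumenal <- class == "photosynthesis"
    # lumenal preproteins carry a <= ~105-residue presequence ahead of a
    # mature domain that dominates quantitation, so draw them longer
    target_len <- ifelse(lumenal, sample(220:400, n, replace = TRUE),
                         sample(100:400, n, replace = TRUE))
    proteins <- vapply(target_len, .random_protein_sequence, character(1L))
    names(proteins) <- ids
    ctp <- ifelse(class == "background", NA_integer_,
                  sample(25:60, n, replace = TRUE))
    ltp <- ifelse(lumenal, ctp + sample(15:45, n, replace = TRUE), NA_integer_)
    compartment <- c(photosynthesis = "thylakoid_lumen",
                     chloroplast_other = "stroma",
                     background = "other")[class]
    terms <- c(photosynthesis = "Photosynthesis;Chloroplast",
               chloroplast_other = "Chloroplast",
               background = "Cytosol")[class]
    annotations <- data.frame(
      protein_id = ids, ctp_end = as.integer(ctp), ltp_end = as.integer(ltp),
      compartment = unname(compartment), terms = unname(terms),
      stringsAsFactors = FALSE
    )
    list(proteins = proteins, annotations = annotations,
         classes = data.frame(protein_id = ids, class = class,
                              stringsAsFactors = FALSE))
  })
}

#' Simulate a peptide-level DIA experiment with known ground truth
#'
#' Each peptide's latent log2 intensity is protein base + class/condition
#' effect + a fixed per-peptide ionization offset + replicate noise.
#' Targeting-region peptides (overlapping residues 1..`ltp_end`, or
#' 1..`ctp_end` for cTP-only proteins) start `targeting_baseline_log2` lower
#' and, for planted accumulators under the affected condition, additionally
#' gain `preprotein_peptide_effect_log2`. Values are exponentiated to the
#' raw scale and masked by intensity-dependent dropout.
#'
#' @param params [simulation_params()].
#' @param proteome output of [generate_proteome()]; regenerated from
#'   `params` when omitted.
#' @return List with elements `matrix` (raw peptide `quant_matrix`),
#'   `peptides` (record table), `design`, `truth` (lists `proteins` and
#'   `peptides` holding every planted effect) and `latent_log2` (pre-masking
#'   latent matrix, for missingness diagnostics).
#' @export
simulate_experiment <- function(params, proteome = generate_proteome(params)) {
  stopifnot(inherits(params, "simulation_params"))
  conds <- names(params$protein_effect_log2)
  design <- do.call(rbind, lapply(conds, function(cond) {
    data.frame(
      sample_id = sprintf("%s_r%d", cond, seq_len(params$n_replicates)),
      genotype = sub("_[^_]*$", "", cond),
      light = sub("^.*_", "", cond),
      replicate = seq_len(params$n_replicates),
      stringsAsFactors = FALSE
    )
  }))
  validate_design(design)
  cond_of_sample <- design_groups(design)
  if (!all(cond_of_sample %in% conds)) {
    stop("condition labels must be of the form genotype_light")
  }
  classes <- proteome$classes
  peptides <- .digest_proteome(proteome$proteins, params)
  validate_peptides(peptides, proteome$proteins)
  ann <- proteome$annotations
  t_end <- ifelse(is.na(ann$ltp_end), ann$ctp_end, ann$ltp_end)
  names(t_end) <- ann$protein_id
  targeting <- !is.na(t_end[peptides$parent]) &
    peptides$start <= t_end[peptides$parent]
  region <- mapply(function(s, e, p) {
    i <- match(p, ann$protein_id)
    map_peptide_to_region(s, e, ann$ctp_end[i], ann$ltp_end[i])$primary
  }, peptides$start, peptides$end, peptides$parent)

  lumenal <- classes$protein_id[classes$class == "photosynthesis"]
  withr::with_seed(params$seed + 1L, {
    accumulators <- params$preprotein_set
    if (is.null(accumulators)) {
      if (params$n_accumulators > length(lumenal)) {
        stop("n_accumulators exceeds number of lumenal proteins")
      }
      accumulators <- sort(sample(lumenal, params$n_accumulators))
    } else if (!all(accumulators %in% lumenal)) {
      stop("preprotein_set must be a subset of lumenal photosynthesis proteins")
    }
    n_pep <- nrow(peptides)
    n_smp <- nrow(design)
    base <- stats::rnorm(nrow(classes), params$base_log2_mean,
                         params$between_protein_sd)
    names(base) <- classes$protein_id
    offset <- stats::rnorm(n_pep, 0, params$peptide_offset_sd) +
      ifelse(targeting, params$targeting_baseline_log2, 0)

    cls <- classes$class[match(peptides$parent, classes$protein_id)]
    latent <- matrix(0, n_pep, n_smp,
                     dimnames = list(peptides$peptide_id, design$sample_id))
    for (j in seq_len(n_smp)) {
      eff <- params$protein_effect_log2[[cond_of_sample[j]]][cls]
      planted <- ifelse(
        targeting & peptides$parent %in% accumulators &
          cond_of_sample[j] == params$preprotein_condition,
        params$preprotein_peptide_effect_log2, 0)
      latent[, j] <- base[peptides$parent] + offset + eff + planted +
        stats::rnorm(n_pep, 0, params$noise_sd)
    }
    values <- 2^latent
    if (params$dropout_prob > 0 && params$mnar_quantile > 0) {
      thresh <- stats::quantile(latent, params$mnar_quantile)
      mask <- latent <= thresh &
        matrix(stats::runif(length(latent)) < params$dropout_prob,
               n_pep, n_smp)
      values[mask] <- NA_real_
    }
  })

  effects <- vapply(conds, function(cond) {
    params$protein_effect_log2[[cond]][classes$class]
  }, numeric(nrow(classes)))
  truth_proteins <- data.frame(
    protein_id = classes$protein_id, class = classes$class,
    is_accumulator = classes$protein_id %in% accumulators,
    stringsAsFactors = FALSE
  )
  truth_proteins[paste0("effect_", conds)] <- as.data.frame(effects)
  pep_effects <- vapply(conds, function(cond) {
    eff <- params$protein_effect_log2[[cond]][cls]
    eff + ifelse(targeting & peptides$parent %in% accumulators &
                   cond == params$preprotein_condition,
                 params$preprotein_peptide_effect_log2, 0)
  }, numeric(nrow(peptides)))
  truth_peptides <- data.frame(
    peptide_id = peptides$peptide_id, parent = peptides$parent,
    region = region, targeting = targeting, stringsAsFactors = FALSE
  )
  truth_peptides[paste0("effect_", conds)] <- as.data.frame(pep_effects)

  list(
    matrix = quant_matrix(values, design, scale = "raw", level = "peptide"),
    peptides = peptides, design = design,
    truth = list(proteins = truth_proteins, peptides = truth_peptides),
    latent_log2 = latent
  )
}
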