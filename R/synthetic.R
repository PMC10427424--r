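#' Synthetic cohort configuration
#'
#' Defines the study conditions the generator emulates: cohort size and
#' responder mix, repertoire depth and clone-frequency skew, the planted
#' clonal dynamics, expression/signature structure, TME subtype mix,
#' neoantigen tables and the confounded two-arm survival design.
#'
#' @param n_patients number of patients (default 18, the size of the
#'   translational RNA cohort).
#' @param frac_well_responders proportion of well responders.
#' @param repertoire_depth templates per repertoire sample.
#' @param n_clones unique clonotypes per sample.
#' @param powerlaw_exponent positive exponent of the truncated power-law
#'   clone-frequency profile (frequency of clone i proportional to
#'   `i^-exponent`).
#' @param itc_overlap_frac proportion of pre-treatment clones persisting
#'   into the post-treatment tumor.
#' @param frac_expanded,frac_contracted fractions of the persistent
#'   clones planted as expanded / contracted (the rest are stable).
#' @param expansion_factor_well,expansion_factor_poor frequency
#'   multipliers for planted-expanded clones by responder status.
#' @param contraction_factor frequency multiplier for planted-contracted
#'   clones.
#' @param new_clone_frac number of new post-treatment clonotypes as a
#'   fraction of `n_clones`.
#' @param new_clone_space total pre-normalization frequency mass of the
#'   new clonotypes.
#' @param nonproductive_frac fraction of clonotypes given a
#'   nonproductive CDR3 (QC spike-ins).
#' @param n_genes genes in the expression matrix.
#' @param signature_effect_size planted group difference (log2 units) on
#'   the signature genes.
#' @param n_signature_genes planted informative IFN/EMT genes.
#' @param expression_sd within-group log2 expression s.d.
#' @param subtype_proportions length-3 vector of TME subtype proportions
#'   (IE, tumor-proliferation, fibroblast-enriched), summing to 1.
#' @param tme_effect_size planted hallmark shift (log2 units on hallmark
#'   genes) separating TME subtypes.
#' @param n_neoantigens neoantigens per timepoint per patient.
#' @param binder_enrichment_well,binder_enrichment_poor expected number
#'   of true binder TCR-neoantigen pairs per patient by responder
#'   status.
#' @param arm_hr hazard ratio of the experimental arm versus the
#'   historical arm (1 = null effect).
#' @param stage_hr hazard ratio of advanced (III) versus early (II)
#'   clinical stage, the planted confounder.
#' @param confounding_beta log-odds shift of experimental-arm assignment
#'   for stage III patients (arm-stage confounding).
#' @param base_median_os baseline median overall survival, months.
#' @param censor_time administrative censoring time, months.
#' @param seed master seed; split deterministically into per-component
#'   streams.
#' @return a `cohort_config` list, validated.
#' @export
cohort_config <- function(n_patients = 18,
                          frac_well_responders = 0.5,
                          repertoire_depth = 1e5,
                          n_clones = 1000,
                          powerlaw_exponent = 1.0,
                          itc_overlap_frac = 0.5,
                          frac_expanded = 0.25,
                          frac_contracted = 0.50,
                          expansion_factor_well = 5,
                          expansion_factor_poor = 1.5,
                          contraction_factor = 0.3,
                          new_clone_frac = 0.35,
                          new_clone_space = 0.25,
                          nonproductive_frac = 0,
                          n_genes = 2000,
                          signature_effect_size = 2,
                          n_signature_genes = 3,
                          expression_sd = 0.5,
                          subtype_proportions = c(1, 1, 1) / 3,
                          tme_effect_size = 2,
                          n_neoantigens = 30,
                          binder_enrichment_well = 12,
                          binder_enrichment_poor = 3,
                          arm_hr = 1,
                          stage_hr = 2,
                          confounding_beta = 1.5,
                          base_median_os = 30,
                          censor_time = 36,
                          seed = 1L) {
  cfg <- as.list(environment())
  props <- c(cfg$frac_well_responders, cfg$itc_overlap_frac,
             cfg$frac_expanded, cfg$frac_contracted,
             cfg$new_clone_frac, cfg$nonproductive_frac)
  if (any(props < 0 | props > 1))
    stop("all proportions must lie in [0, 1]")
  if (cfg$frac_expanded + cfg$frac_contracted > 1)
    stop("frac_expanded + frac_contracted must not exceed 1")
  if (abs(sum(cfg$subtype_proportions) - 1) > 1e-9)
    stop("subtype_proportions must sum to 1")
  if (length(cfg$subtype_proportions) != 3)
    stop("subtype_proportions must have length 3")
  if (cfg$n_patients < 1 || cfg$repertoire_depth < 1 || cfg$n_clones < 1 ||
      cfg$n_genes < 1)
    stop("sizes and depths must be positive")
  if (cfg$powerlaw_exponent <= 0) stop("powerlaw_exponent must be positive")
  if (cfg$repertoire_depth < cfg$n_clones)
    stop("repertoire_depth must be at least n_clones")
  structure(cfg, class = "cohort_config")
}

# deterministic per-component seed derived from the master seed
split_seed <- function(seed, component) {
  h <- sum(utf8ToInt(component) * seq_along(utf8ToInt(component)))
  as.integer((as.numeric(seed) * 48271 + h * 1009) %% 2147483629)
}

zipf_profile <- function(n, exponent) {
  w <- seq_len(n)^(-exponent)
  w / sum(w)
}

random_cdr3aa <- function(n, lengths = NULL) {
  aa <- strsplit("ACDEFGHIKLMNPQRSTVY", "")[[1]]
  if (is.null(lengths)) lengths <- sample(8:16, n, replace = TRUE)
  vapply(seq_len(n), function(i) {
    mid <- paste(sample(aa, lengths[i] - 2, replace = TRUE), collapse = "")
    paste0("C", mid, sample(c("F", "W"), 1))
  }, character(1))
}

make_nonproductive <- function(cdr3) {
  # three explicit failure modes, cycled: stop codon, frameshift, short
  mode <- (seq_along(cdr3) - 1L) %% 3L
  out <- cdr3
  out[mode == 0] <- sub("^(C.)", "\\1*", out[mode == 0])
  out[mode == 1] <- sub("^(C.)", "\\1_", out[mode == 1])
  out[mode == 2] <- substr(out[mode == 2], 1, 4)
  out
}

random_segments <- function(n) {
  list(v = paste0("TRBV", sample(1:30, n, replace = TRUE)),
       d = sample(c(".", "TRBD1", "TRBD2"), n, replace = TRUE),
       j = paste0("TRBJ", sample(1:2, n, replace = TRUE), "-",
                  sample(1:6, n, replace = TRUE)))
}

new_clone_records <- function(n) {
  if (n == 0)
    return(data.frame(cdr3aa = character(0), cdr3nt = character(0),
                      v = character(0), d = character(0),
                      j = character(0), stringsAsFactors = FALSE))
  # unique (cdr3aa, v, j) identities; resample collisions
  seg <- random_segments(n)
  aa <- random_cdr3aa(n)
  nt <- vapply(nchar(aa), function(L)
    paste(sample(c("A", "C", "G", "T"), 3 * L, replace = TRUE),
          collapse = ""), character(1))
  rec <- data.frame(cdr3aa = aa, cdr3nt = nt, v = seg$v, d = seg$d,
                    j = seg$j, stringsAsFactors = FALSE)
  key <- paste(rec$cdr3aa, rec$v, rec$j, sep = "|")
  while (anyDuplicated(key)) {
    i <- which(duplicated(key))
    rec$cdr3aa[i] <- random_cdr3aa(length(i))
    key <- paste(rec$cdr3aa, rec$v, rec$j, sep = "|")
  }
  rec
}

#' Generate a synthetic TCR repertoire
#'
#' Clone frequencies follow a truncated power law (`i^-exponent`,
#' normalized) and counts are a single multinomial draw of `depth`
#' templates. CDR3 amino-acid strings are productive by construction
#' except for an explicit, labeled nonproductive fraction used for QC
#' tests.
#'
#' @param n_clones number of unique clonotypes (>= 1).
#' @param depth total templates (>= n_clones).
#' @param exponent positive power-law exponent.
#' @param seed integer seed (deterministic output).
#' @param nonproductive_frac fraction of clones given nonproductive
#'   CDR3s.
#' @inheritParams clonotype_table
#' @return a `clonotype_table` whose counts sum to `depth`.
#' @export
generate_repertoire <- function(n_clones, depth, exponent = 1.0, seed = 1L,
                                nonproductive_frac = 0,
                                patient = NA_character_,
                                compartment = NA_character_,
                                timepoint = NA_character_) {
  if (n_clones < 1 || depth < n_clones)
    stop("invalid sizes: need n_clones >= 1 and depth >= n_clones")
  withr::with_seed(seed, {
    rec <- new_clone_records(n_clones)
    n_bad <- round(nonproductive_frac * n_clones)
    if (n_bad > 0) {
      idx <- seq_len(n_bad)
      rec$cdr3aa[idx] <- make_nonproductive(rec$cdr3aa[idx])
    }
    p <- zipf_profile(n_clones, exponent)
    counts <- draw_counts_all_present(n_clones, depth, p)
    rec$count <- counts
    clonotype_table(rec, patient = patient, compartment = compartment,
                    timepoint = timepoint)
  })
}

# multinomial draw conditioned on every clone being observed at least once
draw_counts_all_present <- function(n, depth, p) {
  counts <- as.numeric(stats::rmultinom(1, depth - n, p)) + 1
  counts
}

#' Generate paired pre/post tumor repertoires with planted dynamics
#'
#' A fraction `itc_overlap_frac` of the pre-treatment clones persists
#' into the post-treatment tumor. Among the persistent clones,
#' `frac_expanded` are multiplied by the responder-specific expansion
#' factor, `frac_contracted` by `contraction_factor`, the rest kept
#' stable; new clonotypes are added with total mass `new_clone_space`;
#' frequencies are renormalized and counts redrawn at the configured
#' depth.
#'
#' @param config a [cohort_config()].
#' @param responder `"well"` or `"poor"`.
#' @param seed integer seed.
#' @param patient patient id stamped on both tables.
#' @return list with `pre`, `post` (clonotype tables) and `truth`, a data
#'   frame with `key` and planted `category`
#'   (expanded/contracted/stable/new/lost).
#' @export
generate_paired_tumor_repertoires <- function(config, responder = "well",
                                              seed = 1L,
                                              patient = "P1") {
  stopifnot(inherits(config, "cohort_config"))
  responder <- match.arg(responder, c("well", "poor"))
  withr::with_seed(seed, {
    n <- config$n_clones
    pre <- generate_repertoire(n, config$repertoire_depth,
                               config$powerlaw_exponent,
                               seed = split_seed(seed, "pre"),
                               nonproductive_frac = config$nonproductive_frac,
                               patient = patient, compartment = "tumor",
                               timepoint = "baseline")
    keys_pre <- clone_keys(pre)
    n <- nrow(pre)   # may differ from n_clones if QC spike-ins merged
    n_keep <- round(config$itc_overlap_frac * n)
    keep <- sample(seq_len(n), n_keep)
    n_exp <- round(config$frac_expanded * n_keep)
    n_con <- round(config$frac_contracted * n_keep)
    lab <- rep("stable", n_keep)
    if (n_keep > 0) {
      lab[seq_len(n_exp)] <- "expanded"
      if (n_con > 0) lab[n_exp + seq_len(n_con)] <- "contracted"
    }
    ef <- if (responder == "well") config$expansion_factor_well
          else config$expansion_factor_poor
    fac <- c(expanded = ef, contracted = config$contraction_factor,
             stable = 1)[lab]
    w_persist <- pre$freq[keep] * fac

    n_new <- round(config$new_clone_frac * n)
    stable_mass <- sum(pre$freq[keep][lab == "stable"])
    rec_new <- new_clone_records(n_new)
    # avoid key collisions with persistent clones
    key_new <- paste(rec_new$cdr3aa, rec_new$v, rec_new$j, sep = "|")
    while (any(key_new %in% keys_pre)) {
      i <- which(key_new %in% keys_pre)
      rec_new$cdr3aa[i] <- random_cdr3aa(length(i))
      key_new <- paste(rec_new$cdr3aa, rec_new$v, rec_new$j, sep = "|")
    }
    w_new <- if (n_new > 0)
      zipf_profile(n_new, config$powerlaw_exponent) *
        config$new_clone_space else numeric(0)

    # planted-stable clones keep their relative frequency exactly: the
    # expanded/contracted/new masses absorb the renormalization, so the
    # per-clone Fisher null is true for stable clones by construction
    w <- c(w_persist, w_new)
    moving <- c(lab != "stable", rep(TRUE, n_new))
    mv_sum <- sum(w[moving])
    if (mv_sum > 0 && stable_mass < 1)
      w[moving] <- w[moving] * (1 - stable_mass) / mv_sum
    p_post <- w / sum(w)
    n_post <- length(p_post)
    counts <- draw_counts_all_present(n_post, config$repertoire_depth,
                                      p_post)
    rec_post <- rbind(
      as.data.frame(pre)[keep, c("cdr3aa", "cdr3nt", "v", "d", "j")],
      rec_new[, c("cdr3aa", "cdr3nt", "v", "d", "j")])
    rec_post$count <- counts
    post <- clonotype_table(rec_post, patient = patient,
                            compartment = "tumor",
                            timepoint = "post_surgery")
    truth <- rbind(
      data.frame(key = keys_pre[keep], category = lab,
                 stringsAsFactors = FALSE),
      data.frame(key = key_new,
                 category = rep("new", length(key_new)),
                 stringsAsFactors = FALSE),
      data.frame(key = keys_pre[setdiff(seq_len(n), keep)],
                 category = rep("lost", n - n_keep),
                 stringsAsFactors = FALSE))
    list(pre = pre, post = post, truth = truth)
  })
}

#' Generate a longitudinal blood series with circulating ITCs
#'
#' A configured subset of the ITC clonotypes is seeded into each blood
#' repertoire with frequency mass following the per-timepoint scale
#' factors (for example a rise to a peak at W6), on top of background
#' clones drawn from the power-law profile.
#'
#' @param itcs data frame of ITC clonotype records (columns `cdr3aa`,
#'   `cdr3nt`, `v`, `d`, `j`), e.g. rows of a tumor table.
#' @param timepoints character vector of blood timepoints.
#' @param dynamics per-timepoint positive scale factors (same length).
#' @param seed integer seed.
#' @param depth templates per blood sample.
#' @param n_background background blood clonotypes.
#' @param circulating_frac fraction of ITC clones seeded into blood.
#' @param base_space total circulating-ITC frequency mass at scale
#'   factor 1.
#' @param exponent power-law exponent for background and circulating
#'   profiles.
#' @param patient patient id.
#' @return list of `clonotype_table`s, one per timepoint, in order.
#' @export
generate_blood_series <- function(itcs, timepoints, dynamics, seed = 1L,
                                  depth = 1e5, n_background = 500,
                                  circulating_frac = 0.5,
                                  base_space = 0.05, exponent = 1.0,
                                  patient = NA_character_) {
  if (length(timepoints) == 0) stop("timepoints must be nonempty")
  stopifnot(length(dynamics) == length(timepoints), all(dynamics >= 0))
  if (circulating_frac < 0 || circulating_frac > 1)
    stop("circulating_frac must lie in [0, 1]")
  withr::with_seed(seed, {
    n_circ <- round(circulating_frac * nrow(itcs))
    circ <- itcs[sample(seq_len(nrow(itcs)), n_circ), , drop = FALSE]
    w_circ0 <- if (n_circ > 0)
      zipf_profile(n_circ, exponent) * base_space else numeric(0)
    bg <- new_clone_records(n_background)
    key_circ <- paste(circ$cdr3aa, circ$v, circ$j, sep = "|")
    key_bg <- paste(bg$cdr3aa, bg$v, bg$j, sep = "|")
    while (any(key_bg %in% key_circ)) {
      i <- which(key_bg %in% key_circ)
      bg$cdr3aa[i] <- random_cdr3aa(length(i))
      key_bg <- paste(bg$cdr3aa, bg$v, bg$j, sep = "|")
    }
    w_bg <- zipf_profile(n_background, exponent)
    lapply(seq_along(timepoints), function(t) {
      w <- c(w_circ0 * dynamics[t], w_bg)
      p <- w / sum(w)
      rec <- rbind(circ[, c("cdr3aa", "cdr3nt", "v", "d", "j")],
                   bg[, c("cdr3aa", "cdr3nt", "v", "d", "j")])
      keep <- p > 0
      rec <- rec[keep, , drop = FALSE]
      p <- p[keep]
      rec$count <- draw_counts_all_present(nrow(rec), depth, p)
      clonotype_table(rec, patient = patient, compartment = "blood",
                      timepoint = timepoints[t])
    })
  })
}

#' Generate synthetic hallmark score profiles for TME subtyping
#'
#' Direct simulation of the hallmark ssGSEA score matrix: each sample's
#' subtype shifts its defining hallmark group upward by `shift` z-units
#' over standard-normal noise.
#'
#' @param n_samples number of samples.
#' @param proportions length-3 subtype proportions (IE,
#'   tumor-proliferation, fibroblast-enriched).
#' @param shift between-group hallmark shift in z-units.
#' @param seed integer seed.
#' @param hallmark_groups named list of hallmark groups.
#' @return list with `scores` (hallmarks x samples) and `subtype` (true
#'   labels).
#' @export
generate_tme_scores <- function(n_samples, proportions = c(1, 1, 1) / 3,
                                shift = 2, seed = 1L,
                                hallmark_groups = default_hallmark_groups()) {
  stopifnot(abs(sum(proportions) - 1) < 1e-9, length(proportions) == 3)
  withr::with_seed(seed, {
    hm <- unique(unlist(hallmark_groups))
    subtype <- sample(names(hallmark_groups), n_samples, replace = TRUE,
                      prob = proportions)
    scores <- matrix(stats::rnorm(length(hm) * n_samples),
                     nrow = length(hm),
                     dimnames = list(hm, paste0("S", seq_len(n_samples))))
    for (i in seq_len(n_samples)) {
      g <- hallmark_groups[[subtype[i]]]
      scores[g, i] <- scores[g, i] + shift
    }
    list(scores = scores, subtype = subtype)
  })
}

#' Generate expression, clinical, neoantigen and TCR-pair tables
#'
#' Builds the full non-repertoire side of the synthetic cohort:
#' \itemize{
#' \item an expression matrix (genes x patients, log2(FPKM+1)) with
#'   planted responder shifts of `signature_effect_size` on the
#'   designated IFN/EMT signature genes and hallmark-coherent shifts
#'   defining three TME subtypes;
#' \item synthetic gene sets (IFN-alpha, IFN-gamma, EMT and the
#'   subtype-defining hallmark sets) over the synthetic gene universe;
#' \item a clinical table with residual-tumor percentages consistent
#'   with the responder labels, a two-arm design with stage-confounded
#'   arm assignment and exponential survival times;
#' \item neoantigen and TCR-pair tables with a configured true-binder
#'   enrichment in well responders.
#' }
#'
#' @param config a [cohort_config()].
#' @param seed integer seed.
#' @return list with `expression`, `gene_sets`, `clinical`, `mutations`,
#'   `neoantigens`, `pairs` and `truth` (responder labels, signature
#'   genes, subtypes, true-binder flags).
#' @export
generate_expression_and_clinical <- function(config, seed = 1L) {
  stopifnot(inherits(config, "cohort_config"))
  withr::with_seed(seed, {
    n <- config$n_patients
    patients <- sprintf("P%02d", seq_len(n))
    n_well <- round(config$frac_well_responders * n)
    responder <- sample(c(rep("well", n_well), rep("poor", n - n_well)))

    ## gene universe and synthetic gene sets
    genes <- sprintf("G%04d", seq_len(config$n_genes))
    groups <- default_hallmark_groups()
    hm_names <- unlist(groups, use.names = FALSE)
    set_size <- 20
    need <- length(hm_names) * set_size + 120 + config$n_signature_genes
    if (config$n_genes < need)
      stop("n_genes too small for the planted gene sets (need >= ", need, ")")
    pool <- genes
    take <- function(k) {
      out <- pool[seq_len(k)]
      pool <<- pool[-seq_len(k)]
      out
    }
    hallmark_sets <- stats::setNames(
      lapply(hm_names, function(h) take(set_size)), hm_names)
    sig_genes <- take(config$n_signature_genes)
    # signature genes belong to the IFN-gamma set; plus inert decoy members
    ifn_gamma <- c(hallmark_sets$HALLMARK_INTERFERON_GAMMA_RESPONSE,
                   sig_genes, take(40))
    ifn_alpha <- c(hallmark_sets$HALLMARK_INTERFERON_ALPHA_RESPONSE,
                   take(40))
    emt <- c(hallmark_sets$HALLMARK_EPITHELIAL_MESENCHYMAL_TRANSITION,
             take(40))
    gene_sets <- c(hallmark_sets,
                   list(IFN_GAMMA = ifn_gamma, IFN_ALPHA = ifn_alpha,
                        EMT = emt))

    ## expression: baseline per-gene mean + noise + planted shifts
    base <- stats::runif(config$n_genes, 2, 8)
    expr <- matrix(stats::rnorm(config$n_genes * n, mean = base,
                                sd = config$expression_sd),
                   nrow = config$n_genes,
                   dimnames = list(genes, patients))
    expr[sig_genes, responder == "well"] <-
      expr[sig_genes, responder == "well"] + config$signature_effect_size

    subtype <- sample(names(groups), n, replace = TRUE,
                      prob = config$subtype_proportions)
    for (i in seq_len(n)) {
      gset <- unlist(hallmark_sets[groups[[subtype[i]]]])
      expr[gset, i] <- expr[gset, i] + config$tme_effect_size
    }
    expr <- pmax(expr, 0)

    ## clinical: residual tumor coupled to responder label
    residual <- ifelse(responder == "well",
                       round(stats::rbeta(n, 1.2, 3) * 33, 1),
                       round(34 + stats::rbeta(n, 2, 2) * 60, 1))
    stage <- sample(c("II", "III"), n, replace = TRUE)
    site <- sample(c("upper", "middle", "lower"), n, replace = TRUE)
    lp <- -config$confounding_beta / 2 +
      config$confounding_beta * (stage == "III")
    arm <- ifelse(stats::runif(n) < stats::plogis(lp), "nAde", "historical")
    rate0 <- log(2) / config$base_median_os
    rate <- rate0 * config$stage_hr^(stage == "III") *
      config$arm_hr^(arm == "nAde")
    t_event <- stats::rexp(n, rate)
    os_time <- pmin(t_event, config$censor_time)
    os_event <- as.integer(t_event <= config$censor_time)
    rfs_raw <- t_event * stats::runif(n, 0.6, 1)
    rfs_time <- pmin(rfs_raw, config$censor_time)
    rfs_event <- as.integer(rfs_raw <= config$censor_time)
    clinical <- data.frame(
      patient = patients, responder = responder,
      residual_tumor_percent = residual, stage = stage, site = site,
      arm = arm, os_time = os_time, os_event = os_event,
      rfs_time = rfs_time, rfs_event = rfs_event,
      tme_subtype = subtype, stringsAsFactors = FALSE)

    ## mutations -> neoantigens -> TCR pairs
    mk_rows <- function(pt, is_well) {
      m <- config$n_neoantigens
      pre <- stats::runif(m) < 0.75
      post <- ifelse(pre, stats::runif(m) < 0.6, TRUE)
      mut <- data.frame(
        patient = pt,
        mutation = sprintf("%s_MUT%03d", pt, seq_len(m)),
        gene = sample(genes, m, replace = TRUE),
        pre = pre, post = post, nonsynonymous = stats::runif(m) < 0.9,
        stringsAsFactors = FALSE)
      neo <- data.frame(
        patient = pt,
        peptide = vapply(seq_len(m), function(i)
          paste(sample(strsplit("ACDEFGHIKLMNPQRSTVY", "")[[1]], 9,
                       replace = TRUE), collapse = ""), character(1)),
        allele = sample(c("HLA-A*02:01", "HLA-A*11:01", "HLA-B*15:01"),
                        m, replace = TRUE),
        mutation = mut$mutation,
        affinity_nM = exp(stats::rnorm(m, log(400), 1.1)),
        stringsAsFactors = FALSE)
      n_binder <- stats::rpois(1, if (is_well)
        config$binder_enrichment_well else config$binder_enrichment_poor)
      n_decoy <- 40
      clono <- sprintf("%s_CLONE%03d", pt,
                       sample(200, n_binder + n_decoy, replace = TRUE))
      pairs <- data.frame(
        patient = pt,
        clonotype = clono,
        peptide = sample(neo$peptide, n_binder + n_decoy, replace = TRUE),
        rank = c(stats::runif(n_binder, 0.01, 2),
                 stats::runif(n_decoy, 2, 100)),
        true_binder = c(rep(TRUE, n_binder), rep(FALSE, n_decoy)),
        stringsAsFactors = FALSE)
      list(mut = mut, neo = neo, pairs = pairs)
    }
    per <- lapply(seq_len(n), function(i)
      mk_rows(patients[i], responder[i] == "well"))
    mutations <- do.call(rbind, lapply(per, `[[`, "mut"))
    neoantigens <- do.call(rbind, lapply(per, `[[`, "neo"))
    pairs <- do.call(rbind, lapply(per, `[[`, "pairs"))

    list(expression = expr, gene_sets = gene_sets, clinical = clinical,
         mutations = mutations, neoantigens = neoantigens, pairs = pairs,
         truth = list(responder = stats::setNames(responder, patients),
                      signature_genes = sig_genes,
                      subtype = stats::setNames(subtype, patients)))
  })
}

#' Generate and write a complete synthetic cohort
#'
#' Runs the repertoire, blood, expression and clinical generators for the
#' whole cohort and writes every standard-format table under `outdir`:
#' VDJtools-style clonotype TSVs, an expression TSV, gene sets as GMT,
#' MAF-like mutation TSV, neoantigen/pair TSVs, a clinical TSV and the
#' planted ground truth as JSON.
#'
#' @param config a [cohort_config()].
#' @param outdir output directory (created if needed).
#' @param seed master seed; per-component seeds are derived from it.
#' @return invisibly, the list of generated objects.
#' @export
simulate_cohort <- function(config = cohort_config(), outdir,
                            seed = config$seed) {
  stopifnot(inherits(config, "cohort_config"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  omics <- generate_expression_and_clinical(
    config, seed = split_seed(seed, "omics"))
  reps <- lapply(seq_len(config$n_patients), function(i) {
    pt <- omics$clinical$patient[i]
    generate_paired_tumor_repertoires(
      config, responder = omics$clinical$responder[i],
      seed = split_seed(seed, paste0("rep", i)), patient = pt)
  })
  names(reps) <- omics$clinical$patient

  for (i in seq_along(reps)) {
    pt <- names(reps)[i]
    write_clonotype_table(reps[[i]]$pre,
                          file.path(outdir, paste0(pt, "_tumor_baseline.tsv")))
    write_clonotype_table(reps[[i]]$post,
                          file.path(outdir, paste0(pt, "_tumor_post.tsv")))
  }
  expr_df <- data.frame(gene = rownames(omics$expression),
                        omics$expression, check.names = FALSE)
  utils::write.table(expr_df, file.path(outdir, "expression.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_gmt(omics$gene_sets, file.path(outdir, "gene_sets.gmt"))
  for (nm in c("clinical", "mutations", "neoantigens", "pairs"))
    utils::write.table(omics[[nm]], file.path(outdir, paste0(nm, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  truth <- c(omics$truth,
             list(clone_categories = lapply(reps, `[[`, "truth")))
  jsonlite::write_json(truth, file.path(outdir, "ground_truth.json"),
                       digits = NA, auto_unbox = FALSE)
  invisible(list(repertoires = reps, omics = omics))
}
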