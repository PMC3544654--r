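#' Seeded generators for every pipeline input
#'
#' The generators emulate the statistical structure the analysis assumes:
#' family gain as a Poisson birth process on the focal lineage with
#' Gamma-distributed lifespans; sequence evolution under K80 with
#' age-dependent rates (young families evolve faster); SNP/indel placement at
#' per-region densities (mature < precursor < flank); expression atlases whose
#' tissue specificity decreases and abundance increases with age; and
#' target/host maps with increasing target multiplicity and a fixed intronic
#' propensity. A fixed seed makes every generator byte-reproducible.
#'
#' @name synthetic_data
NULL

#' Simulation configuration
#'
#' Defaults are the study conditions the analysis is calibrated around:
#' birth rate 40 families/Myr with Gamma(shape 2) lifespans scaled so that 5%
#' of families survive 100 Myr; flank substitution rate 0.002
#' subs/site/Myr for the oldest groups with a 3:1 young:old ratio and region
#' multipliers flank 1 > precursor 0.6 > mature 0.3; 12 tissues with Dirichlet
#' concentration rising (and so specificity falling) and log-abundance rising
#' from young to old; variant densities flank 0.008 > precursor 0.004 >
#' mature 0.002 records per bp with 20% indels; target means rising from 5
#' (young) to 40 (old) over a 2000-gene universe; intronic probability 0.63.
#'
#' @param seed integer seed; fixed seed implies identical output.
#' @param tree a [species_tree()]; default the packaged 11-taxon tree.
#' @param v birth rate per Myr.
#' @param shape,scale Gamma lifespan parameters; `scale = NULL` solves the
#'   scale so that `P(surv_horizon) = surv_p`.
#' @param surv_horizon,surv_p horizon (Myr) and survivorship used when
#'   `scale` is `NULL`.
#' @param rate_flank_old,rate_ratio_young flank substitution rate of the
#'   oldest group (subs/site/Myr) and the young:old rate ratio.
#' @param class_multipliers named rate multipliers for the region classes.
#' @param kappa K80 transition/transversion rate ratio.
#' @param n_tissues,lib_depth,malignant_boost_young expression atlas shape.
#' @param conc_young,conc_old Dirichlet concentrations (per tissue) for the
#'   youngest and oldest groups (log-interpolated between).
#' @param abund_young,abund_old median maximal abundance scale for the
#'   youngest and oldest groups (log-interpolated).
#' @param variant_density_cfg named per-bp variant-record densities (SNPs and
#'   indels together) by region class.
#' @param indel_fraction fraction of variant records that are indels.
#' @param nmfe_mean,nmfe_sd_old,nmfe_var_ratio_young NMFE generator: common
#'   mean (kcal/mol/nt) and oldest-group s.d., with the young:old variance
#'   ratio (default 6).
#' @param n_genes,mean_targets_young,mean_targets_old,shared_gene_frac target
#'   generator: universe size, per-miRNA target means, and the fraction of
#'   the universe forming the shared pool that induces cross-age overlap.
#' @param shared_p probability a target is drawn from the shared pool.
#' @param intronic_p probability a miRNA is intronic (hosted).
#' @param oldest_host_p probability a host gene is in the oldest host-age
#'   class (of `n_host_ages` classes).
#' @param n_host_ages number of host-gene age classes.
#' @param homoplasy_rate per-tip independent loss probability (stress knob;
#'   0 keeps profiles homoplasy-free so parsimony recovery is exact).
#' @return a `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       tree = default_species_tree(),
                       v = 40,
                       shape = 2,
                       scale = NULL,
                       surv_horizon = 100,
                       surv_p = 0.05,
                       rate_flank_old = 0.002,
                       rate_ratio_young = 3,
                       class_multipliers = c(mature = 0.3, precursor_nonmature = 0.6, flank = 1),
                       kappa = 2,
                       n_tissues = 12,
                       lib_depth = 5000,
                       malignant_boost_young = 2,
                       conc_young = 0.15,
                       conc_old = 2,
                       abund_young = 0.002,
                       abund_old = 0.03,
                       variant_density_cfg = c(mature = 0.002, precursor_nonmature = 0.004, flank = 0.008),
                       indel_fraction = 0.2,
                       nmfe_mean = -0.45,
                       nmfe_sd_old = 0.03,
                       nmfe_var_ratio_young = 6,
                       n_genes = 2000,
                       mean_targets_young = 5,
                       mean_targets_old = 40,
                       shared_gene_frac = 0.1,
                       shared_p = 0.3,
                       intronic_p = 0.63,
                       oldest_host_p = 0.75,
                       n_host_ages = 6,
                       homoplasy_rate = 0) {
  if (is.null(scale)) scale <- bd_scale_for_survival(shape, surv_horizon, surv_p)
  cfg <- list(
    seed = as.integer(seed), tree = tree, v = v, shape = shape, scale = scale,
    rate_flank_old = rate_flank_old, rate_ratio_young = rate_ratio_young,
    class_multipliers = class_multipliers, kappa = kappa,
    n_tissues = n_tissues, lib_depth = lib_depth,
    malignant_boost_young = malignant_boost_young,
    conc_young = conc_young, conc_old = conc_old,
    abund_young = abund_young, abund_old = abund_old,
    variant_density_cfg = variant_density_cfg, indel_fraction = indel_fraction,
    nmfe_mean = nmfe_mean, nmfe_sd_old = nmfe_sd_old,
    nmfe_var_ratio_young = nmfe_var_ratio_young,
    n_genes = n_genes, mean_targets_young = mean_targets_young,
    mean_targets_old = mean_targets_old, shared_gene_frac = shared_gene_frac,
    shared_p = shared_p, intronic_p = intronic_p,
    oldest_host_p = oldest_host_p, n_host_ages = n_host_ages,
    homoplasy_rate = homoplasy_rate
  )
  stopifnot(v >= 0, all(unlist(cfg$variant_density_cfg) >= 0))
  structure(cfg, class = "sim_config")
}

# per-age-group value interpolated from youngest to oldest on log scale
age_interp <- function(young, old, k, log_scale = TRUE) {
  w <- seq(0, 1, length.out = k + 1)
  if (log_scale) exp(log(young) + w * (log(old) - log(young)))
  else young + w * (old - young)
}

# stepwise substitution-rate profile by age group: the young groups run at
# rate_ratio_young times the old groups' flank rate, with a geometric middle
# step, so the young:old contrast equals the configured ratio exactly. For
# the 8-interval tree the steps follow the default young/middle/old merge.
age_rate_profile <- function(config, k) {
  r <- config$rate_ratio_young
  base <- config$rate_flank_old
  if (k == 7) {
    mult <- c(rep(r, 4), rep(sqrt(r), 2), rep(1, 2))
  } else {
    third <- ceiling((k + 1) / 3)
    mult <- rep(c(r, sqrt(r), 1), times = c(third, third, k + 1 - 2 * third))
  }
  base * mult
}

#' Simulate miRNA family births, survival and presence profiles
#'
#' Births are a Poisson process at rate `v` per Myr along the root-to-focal
#' path; each family's lifespan is Gamma(shape, scale) and only families whose
#' lifespan exceeds their age are extant. An extant family born `s` Myr ago is
#' present in the focal tip and in every tip whose lineage split from the
#' focal lineage more recently than `s` (i.e. all descendants of the origin
#' node); by default there are no secondary losses so parsimony can recover
#' the true origin exactly.
#'
#' Under `ages_from = "process"` the age distribution of extant families is
#' the one the birth-death model predicts, which at the default parameters
#' concentrates almost all extant families in the youngest intervals. The
#' `"census"` mode instead draws family ages from the published age-group
#' census proportions (all eight groups populated, as in the real data),
#' which is the regime the downstream age-group analyses assume.
#'
#' @param config a [sim_config()].
#' @param n_families if given, exactly this many extant families are produced
#'   (ages drawn from the stationary extant-age distribution) instead of a
#'   Poisson number. Required implicitly by `"census"` mode (defaults there to
#'   the census total).
#' @param ages_from `"process"` (birth-death process; default) or `"census"`.
#' @return a list with `profiles` (presence tibble, one row per extant family)
#'   and `truth` (tibble: family, birth_myr, age_index, age_label).
#' @export
simulate_families <- function(config, n_families = NULL,
                              ages_from = c("process", "census")) {
  ages_from <- match.arg(ages_from)
  set.seed(config$seed)
  tree <- config$tree
  tau <- tree$path$time_myr
  horizon <- max(tau)
  births <- numeric(0)
  if (ages_from == "census") {
    census <- published_age_census()
    if (is.null(n_families)) n_families <- sum(census$n_mirnas)
    k <- nrow(tree$path)
    if (nrow(census) != k + 1) abort("census does not match the tree's age intervals")
    idx <- sample(0:k, n_families, replace = TRUE, prob = census$n_mirnas)
    lo <- c(0, tau)[idx + 1]
    hi <- c(tau, max(tau) + 150)[idx + 1]  # oldest interval bounded for sampling
    births <- runif(n_families, lo, hi)
  } else if (is.null(n_families)) {
    n <- rpois(1, config$v * horizon)
    if (n > 0) {
      s <- runif(n, 0, horizon)
      life <- rgamma(n, shape = config$shape, scale = config$scale)
      births <- s[life > s]
    }
  } else {
    while (length(births) < n_families) {
      s <- runif(max(4 * n_families, 100), 0, horizon)
      life <- rgamma(length(s), shape = config$shape, scale = config$scale)
      births <- c(births, s[life > s])
    }
    births <- births[seq_len(n_families)]
  }
  if (!length(births)) {
    return(list(profiles = empty_profiles(tree), truth = tibble(
      family = character(0), birth_myr = numeric(0),
      age_index = integer(0), age_label = character(0)
    )))
  }
  age_idx <- findInterval(births, tau)
  fam <- sprintf("fam%05d", seq_along(births))
  tips <- tree$phylo$tip.label
  prof <- matrix("absent", length(births), length(tips),
                 dimnames = list(NULL, tips))
  ntip <- length(tips)
  # tips present for a family with origin at path rank r: descendants of the
  # r-th path node (r = 0: focal tip only)
  tips_by_rank <- lapply(seq_len(nrow(tree$path)), function(r) {
    tips[descendant_tips(tree$phylo, tree$path$node[r])]
  })
  for (i in seq_along(births)) {
    r <- age_idx[i]
    pres <- if (r == 0) tree$focal else tips_by_rank[[r]]
    prof[i, pres] <- "present"
  }
  if (config$homoplasy_rate > 0) {
    nonfocal <- setdiff(tips, tree$focal)
    for (sp in nonfocal) {
      flip <- prof[, sp] == "present" & runif(nrow(prof)) < config$homoplasy_rate
      prof[flip, sp] <- "absent"
    }
  }
  profiles <- dplyr::bind_cols(tibble(family = fam),
                               as_tibble(as.data.frame(prof, check.names = FALSE)))
  truth <- tibble(
    family = fam, birth_myr = births,
    age_index = as.integer(age_idx), age_label = paste0("t", age_idx)
  )
  list(profiles = profiles, truth = truth)
}

empty_profiles <- function(tree) {
  tips <- tree$phylo$tip.label
  out <- c(list(family = character(0)),
           setNames(rep(list(character(0)), length(tips)), tips))
  as_tibble(out)
}

# --- K80 sequence evolution ---------------------------------------------

k80_site_probs <- function(d, kappa) {
  # rates: alpha (transition), beta (each of 4 transversion paths at beta/..)
  bt <- d / (kappa + 2)
  at <- kappa * bt
  p_ts <- 0.25 + 0.25 * exp(-4 * bt) - 0.5 * exp(-2 * (at + bt))
  p_tv_each <- 0.25 - 0.25 * exp(-4 * bt)  # each of the two transversions
  c(ts = p_ts, tv = p_tv_each)
}

DNA <- c("A", "C", "G", "T")
TS_MAP <- c(A = "G", G = "A", C = "T", T = "C")
TV_MAP <- list(A = c("C", "T"), G = c("C", "T"), C = c("A", "G"), T = c("A", "G"))

#' Evolve a sequence under K80
#'
#' @param seq character scalar over A/C/G/T.
#' @param d expected substitutions per site along the branch.
#' @param kappa transition/transversion rate ratio.
#' @return the derived sequence.
#' @export
k80_evolve <- function(seq, d, kappa = 2) {
  if (d < 0) abort("branch length must be >= 0")
  x <- strsplit(seq, "")[[1]]
  if (d == 0) return(seq)
  pr <- k80_site_probs(d, kappa)
  u <- runif(length(x))
  ts <- u < pr["ts"]
  tv1 <- !ts & u < pr["ts"] + pr["tv"]
  tv2 <- !ts & !tv1 & u < pr["ts"] + 2 * pr["tv"]
  x0 <- x  # classify sites on the ancestral base, not in-place
  x[ts] <- unname(TS_MAP[x0[ts]])
  for (b in DNA) {
    x[tv1 & x0 == b] <- TV_MAP[[b]][1]
    x[tv2 & x0 == b] <- TV_MAP[[b]][2]
  }
  paste(x, collapse = "")
}

random_dna <- function(n) paste(sample(DNA, n, replace = TRUE), collapse = "")

# evolve from `node` down to present tips; returns named character vector
evolve_subtree <- function(phy, node, seq, rate, kappa, keep_tips) {
  ntip <- length(phy$tip.label)
  out <- character(0)
  if (node <= ntip) {
    nm <- phy$tip.label[node]
    if (nm %in% keep_tips) out[nm] <- seq
    return(out)
  }
  rows <- which(phy$edge[, 1] == node)
  for (r in rows) {
    child <- phy$edge[r, 2]
    d <- phy$edge.length[r] * rate
    out <- c(out, evolve_subtree(phy, child, k80_evolve(seq, d, kappa), rate, kappa, keep_tips))
  }
  out
}

#' Simulate alignments, region intervals and variants for extant families
#'
#' Each family gets a 200-bp focal locus: 60-bp flanks around an 80-bp
#' precursor holding a 22-nt mature arm. Orthologous sequences for the species
#' carrying the family evolve down the subtree from the origin node under K80,
#' with the per-Myr rate set by the family's age group (young faster) and a
#' region-class multiplier (mature slowest). SNPs/indels are sprinkled on the
#' focal locus at the configured per-class, per-bp densities.
#'
#' @param config a [sim_config()].
#' @param families output of [simulate_families()].
#' @param max_families cap on the number of families given alignments (the
#'   locus simulation dominates runtime); default all.
#' @return a list: `blocks` (tibble: block_id, species, seq, age_label,
#'   class), `records` (miRNA records for the focal species), `intervals`
#'   and `variants` (focal-locus coordinates, 0-based half-open).
#' @export
simulate_alignments <- function(config, families, max_families = NULL) {
  set.seed(config$seed + 1L)
  tree <- config$tree
  truth <- families$truth
  if (!is.null(max_families) && nrow(truth) > max_families) {
    truth <- truth[seq_len(max_families), ]
  }
  k <- nrow(tree$path)
  base_rate <- age_rate_profile(config, k)  # index 1 = age 0 (young, fast)
  # locus layout
  flank_l <- c(0, 60); prec <- c(60, 140); mature <- c(80, 102); flank_r <- c(140, 200)
  blocks <- list(); records <- list(); intervals <- list(); variants <- list()
  segs <- list(
    flank = list(c(flank_l[1], flank_l[2]), c(flank_r[1], flank_r[2])),
    precursor_nonmature = list(c(prec[1], mature[1]), c(mature[2], prec[2])),
    mature = list(mature)
  )
  for (i in seq_len(nrow(truth))) {
    fam <- truth$family[i]
    r <- truth$age_index[i]
    prof <- unlist(families$profiles[families$profiles$family == fam,
                                     tree$phylo$tip.label])
    present <- names(prof)[prof == "present"]
    origin <- if (r == 0) match(tree$focal, tree$phylo$tip.label) else tree$path$node[r]
    locus <- random_dna(200)
    seq_by_class <- list()
    for (cl in names(segs)) {
      rate <- base_rate[r + 1] * config$class_multipliers[[cl]]
      anc <- paste(vapply(segs[[cl]], function(iv) substr(locus, iv[1] + 1, iv[2]), ""),
                   collapse = "")
      tip_seqs <- evolve_subtree(tree$phylo, origin, anc, rate, config$kappa, present)
      seq_by_class[[cl]] <- tip_seqs
      blocks[[length(blocks) + 1]] <- tibble(
        block_id = paste0(fam, "_", cl), species = names(tip_seqs),
        seq = unname(tip_seqs), age_label = truth$age_label[i], class = cl
      )
    }
    # focal precursor record: human precursor = nonmature(left)+mature+nonmature(right)
    hm <- seq_by_class$mature[tree$focal]
    hp <- seq_by_class$precursor_nonmature[tree$focal]
    precursor <- paste0(substr(hp, 1, 20), hm, substr(hp, 21, nchar(hp)))
    records[[length(records) + 1]] <- tibble(
      id = fam, precursor = precursor, mature_start = 20, mature_end = 42,
      age_label = truth$age_label[i]
    )
    intervals[[length(intervals) + 1]] <- tibble(
      seqid = fam,
      start = c(flank_l[1], flank_r[1], prec[1], mature[2], mature[1]),
      end = c(flank_l[2], flank_r[2], mature[1], prec[2], mature[2]),
      class = c("flank", "flank", "precursor_nonmature", "precursor_nonmature", "mature"),
      mirna_id = fam, strand = "+"
    )
    # variants per class at configured density
    for (cl in names(segs)) {
      dens <- config$variant_density_cfg[[cl]]
      for (iv in segs[[cl]]) {
        pos <- (iv[1]:(iv[2] - 1))[runif(iv[2] - iv[1]) < dens]
        if (length(pos)) {
          variants[[length(variants) + 1]] <- tibble(
            seqid = fam, pos = pos,
            type = ifelse(runif(length(pos)) < config$indel_fraction, "indel", "snp"),
            id = paste0("v_", fam, "_", pos)
          )
        }
      }
    }
  }
  list(
    blocks = dplyr::bind_rows(blocks),
    records = dplyr::bind_rows(records),
    intervals = dplyr::bind_rows(intervals),
    variants = if (length(variants)) dplyr::bind_rows(variants) else
      tibble(seqid = character(0), pos = integer(0), type = character(0), id = character(0))
  )
}

rdirichlet1 <- function(alpha) {
  g <- rgamma(length(alpha), shape = alpha, scale = 1)
  if (sum(g) == 0) g[sample.int(length(g), 1)] <- 1
  g / sum(g)
}

#' Simulate an expression atlas
#'
#' Per-miRNA tissue profiles are Dirichlet with concentration rising with age
#' (young = spiky = tissue-specific); per-miRNA abundance scales rise with
#' age; libraries (one normal and one malignant per tissue) draw multinomial
#' clone counts, with young miRNAs' weights boosted in malignant libraries.
#'
#' @param config a [sim_config()].
#' @param families output of [simulate_families()].
#' @return an [expression_atlas()].
#' @export
simulate_atlas <- function(config, families) {
  set.seed(config$seed + 2L)
  truth <- families$truth
  if (!nrow(truth)) abort("no extant families to express")
  k <- nrow(config$tree$path)
  tn <- paste0("tissue", sprintf("%02d", seq_len(config$n_tissues)))
  libs <- tibble(
    library = c(paste0(tn, "_n"), paste0(tn, "_m")),
    tissue = rep(tn, 2),
    state = rep(c("normal", "malignant"), each = config$n_tissues)
  )
  conc <- age_interp(config$conc_young, config$conc_old, k)
  abund <- age_interp(config$abund_young, config$abund_old, k)
  # malignant boost decays from young to old
  boost <- age_interp(config$malignant_boost_young, 1, k)
  n <- nrow(truth)
  profile <- t(vapply(truth$age_index, function(a) {
    rdirichlet1(rep(conc[a + 1], config$n_tissues))
  }, numeric(config$n_tissues)))
  scale_m <- abund[truth$age_index + 1] * exp(rnorm(n, 0, 0.5))
  counts <- matrix(0L, n, nrow(libs), dimnames = list(truth$family, libs$library))
  for (j in seq_len(nrow(libs))) {
    ti <- match(libs$tissue[j], tn)
    w <- scale_m * profile[, ti]
    if (libs$state[j] == "malignant") w <- w * boost[truth$age_index + 1]
    if (sum(w) == 0) next
    counts[, j] <- as.integer(rmultinom(1, config$lib_depth, w / sum(w)))
  }
  expression_atlas(counts, libs)
}

#' Simulate NMFE records
#'
#' A common mean NMFE across age groups with variance shrinking from young to
#' old (default young:old variance ratio 6), reflecting structural
#' optimisation of old precursors.
#'
#' @param config a [sim_config()].
#' @param families output of [simulate_families()].
#' @param length precursor length used for all records (nt).
#' @return a tibble: `mirna`, `age_label`, `length`, `mfe`.
#' @export
simulate_nmfe <- function(config, families, length = 80) {
  set.seed(config$seed + 3L)
  truth <- families$truth
  k <- nrow(config$tree$path)
  sd_by_age <- sqrt(age_interp(config$nmfe_sd_old^2 * config$nmfe_var_ratio_young,
                               config$nmfe_sd_old^2, k))
  nmfe <- config$nmfe_mean + rnorm(nrow(truth), 0, sd_by_age[truth$age_index + 1])
  tibble(
    mirna = truth$family, age_label = truth$age_label,
    length = length, mfe = nmfe * length
  )
}

#' Simulate target maps and host annotations
#'
#' Per-miRNA target counts are Poisson with a mean rising with age; a shared
#' gene pool induces cross-age overlap. Each miRNA is intronic (hosted) with
#' the configured probability; host genes come mostly from the oldest of the
#' host-age classes.
#'
#' @param config a [sim_config()].
#' @param families output of [simulate_families()].
#' @return a list: `targets` (tibble mirna, gene), `hosts` (tibble mirna,
#'   host_gene, host_age, intronic, strand_relation).
#' @export
simulate_targets_hosts <- function(config, families) {
  set.seed(config$seed + 4L)
  truth <- families$truth
  k <- nrow(config$tree$path)
  genes <- sprintf("gene%04d", seq_len(config$n_genes))
  shared <- genes[seq_len(max(1, round(config$shared_gene_frac * config$n_genes)))]
  mt <- age_interp(config$mean_targets_young, config$mean_targets_old, k)
  targets <- purrr::map_dfr(seq_len(nrow(truth)), function(i) {
    nt <- rpois(1, mt[truth$age_index[i] + 1])
    if (nt == 0) return(NULL)
    from_shared <- runif(nt) < config$shared_p
    g <- ifelse(from_shared,
                sample(shared, nt, replace = TRUE),
                sample(genes, nt, replace = TRUE))
    tibble(mirna = truth$family[i], gene = unique(g))
  })
  n <- nrow(truth)
  intronic <- runif(n) < config$intronic_p
  host_ages <- paste0("h", 0:(config$n_host_ages - 1))
  oldest <- host_ages[config$n_host_ages]
  h_age <- ifelse(runif(n) < config$oldest_host_p, oldest,
                  sample(host_ages[-config$n_host_ages], n, replace = TRUE))
  hosts <- tibble(
    mirna = truth$family,
    host_gene = ifelse(intronic, sprintf("host%05d", seq_len(n)), NA_character_),
    host_age = ifelse(intronic, h_age, NA_character_),
    intronic = intronic,
    strand_relation = ifelse(intronic,
                             ifelse(runif(n) < 0.9, "sense", "antisense"),
                             NA_character_)
  )
  list(targets = targets, hosts = hosts)
}

#' Materialise a complete synthetic study directory
#'
#' Runs every generator and writes the exact formats the readers consume:
#' tree (Newick), presence matrix, truth table, precursor FASTA + coordinate
#' table, alignments + sidecar, intervals, variants, atlas counts + metadata,
#' NMFE table, target map and host annotations.
#'
#' @param config a [sim_config()].
#' @param dir output directory (created if needed).
#' @param n_families optional fixed number of extant families.
#' @param max_align_families cap on families given full alignments.
#' @param ages_from age-distribution mode passed to [simulate_families()];
#'   the default `"census"` populates all eight groups as in the real data.
#' @return invisibly, a named list of the written paths.
#' @export
simulate_study <- function(config, dir, n_families = NULL, max_align_families = 150,
                           ages_from = "census") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fam <- simulate_families(config, n_families = n_families, ages_from = ages_from)
  aln <- simulate_alignments(config, fam, max_families = max_align_families)
  atlas <- simulate_atlas(config, fam)
  nmfe <- simulate_nmfe(config, fam)
  th <- simulate_targets_hosts(config, fam)
  p <- function(f) file.path(dir, f)
  write_species_tree(config$tree, p("tree.nwk"))
  write_presence_matrix(fam$profiles, p("presence.tsv"))
  readr::write_tsv(fam$truth, p("truth.tsv"), progress = FALSE)
  write_mirna_records(aln$records, p("precursors.fa"), p("mirna_table.tsv"))
  write_alignments(aln$blocks, p("alignments.fa"), p("alignment_blocks.tsv"))
  write_intervals(aln$intervals, p("intervals.tsv"))
  write_variants(aln$variants, p("variants.tsv"))
  write_expression_atlas(atlas, p("atlas_counts.tsv"), p("atlas_libraries.tsv"))
  readr::write_tsv(nmfe, p("nmfe.tsv"), progress = FALSE)
  readr::write_tsv(th$targets, p("targets.tsv"), progress = FALSE)
  readr::write_tsv(th$hosts, p("hosts.tsv"), progress = FALSE)
  yaml::write_yaml(list(
    tree = "tree.nwk", focal = config$tree$focal, seed = config$seed,
    merge_map = lapply(default_merge_map(nrow(config$tree$path)), as.integer)
  ), p("config.yaml"))
  invisible(setNames(
    as.list(file.path(dir, c("tree.nwk", "presence.tsv", "truth.tsv", "precursors.fa",
                             "mirna_table.tsv", "alignments.fa", "alignment_blocks.tsv",
                             "intervals.tsv", "variants.tsv", "atlas_counts.tsv",
                             "atlas_libraries.tsv", "nmfe.tsv", "targets.tsv",
                             "hosts.tsv", "config.yaml"))),
    c("tree", "presence", "truth", "precursors", "mirna_table", "alignments",
      "alignment_blocks", "intervals", "variants", "atlas_counts",
      "atlas_libraries", "nmfe", "targets", "hosts", "config")
  ))
}
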