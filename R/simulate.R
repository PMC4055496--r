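#' Default species panel for the whitefish survey
#'
#' The gadoid (plus hake and one freshwater contaminant) taxa relevant to a UK
#' whitefish audit. Species sharing a `group` are congener pairs with 100%
#' COI sequence identity (Pacific/Greenland cod; Alaskan/Norwegian pollock)
#' and are treated as a single assignable unit throughout.
#'
#' @return data.frame with columns `species` and `group`.
#' @export
default_species <- function() {
  data.frame(
    species = c("Gadus_morhua", "Gadus_macrocephalus", "Gadus_ogac",
                "Gadus_chalcogrammus", "Gadus_finnmarchica",
                "Melanogrammus_aeglefinus", "Merlangius_merlangus",
                "Micromesistius_poutassou", "Merluccius_capensis",
                "Merluccius_paradoxus", "Pangasius_hypophthalmus"),
    group = c("morhua", "macrocephalus", "macrocephalus",
              "chalcogramma", "chalcogramma",
              "aeglefinus", "merlangus", "poutassou",
              "capensis", "paradoxus", "pangasius"),
    stringsAsFactors = FALSE
  )
}

# Guide tree holding the default pairwise divergence targets (p-distance
# scale). Interspecific distances are all > 2%; congeners sit at 0. The
# haddock lineage is placed sister to whiting (its nearest relative in the
# panel), cod/pollock/Pacific-cod form the Gadus clade, hakes and the
# pangasiid are progressively further out.
default_guide_tree <- function() {
  paste0(
    "(((((Gadus_morhua:0.018,(Gadus_chalcogrammus:0,Gadus_finnmarchica:0)",
    ":0.022):0.007,(Gadus_macrocephalus:0,Gadus_ogac:0):0.029):0.021,",
    "(Melanogrammus_aeglefinus:0.035,Merlangius_merlangus:0.045):0.012)",
    ":0.015,Micromesistius_poutassou:0.06):0.055,",
    "(Merluccius_capensis:0.025,Merluccius_paradoxus:0.028):0.06,",
    "Pangasius_hypophthalmus:0.11);"
  )
}

#' Default pairwise divergence targets for the reference panel
#'
#' Patristic p-distances on the default guide tree; symmetric matrix with zero
#' diagonal. Congener pairs are at exactly 0, all cross-group pairs > 0.02.
#'
#' @return numeric matrix with species dimnames.
#' @export
default_divergences <- function() {
  tr <- ape::read.tree(text = default_guide_tree())
  d <- ape::cophenetic.phylo(tr)
  d[order(rownames(d)), order(colnames(d))]
}

# nearest species outside each species' own group, by target divergence;
# ties broken alphabetically (used by the mixed-composition rule)
derive_sister_map <- function(divergences, species_spec) {
  sp <- species_spec$species
  grp <- setNames(species_spec$group, sp)
  out <- character(0)
  for (s in sp) {
    cand <- sp[grp[sp] != grp[[s]]]
    if (length(cand) == 0) next
    d <- divergences[s, cand]
    out[[s]] <- sort(cand[d == min(d)])[1]
  }
  out
}

#' Simulate a COI reference panel with controlled divergences
#'
#' Generates one reference sequence per species such that every realized
#' pairwise p-distance is within 0.005 of its target. Targets must form an
#' additive (tree-like) metric: the generator fits a neighbour-joining tree to
#' the target matrix and plants disjoint mutated site sets on each branch, so
#' p-distances add exactly along paths (each variable site changes exactly
#' once on the tree). Congener pairs (target 0) come out byte-identical.
#'
#' @param species_spec data.frame with columns `species`, `group`.
#' @param divergence_spec symmetric matrix of target p-distances in
#'   `[0, 0.25]` with species dimnames.
#' @param length sequence length in bases (>= 100).
#' @param seed integer seed; fixed seed gives byte-identical output.
#' @return A `reference_panel` object (see [reference_panel()]).
#' @export
simulate_reference_panel <- function(species_spec = default_species(),
                                     divergence_spec = default_divergences(),
                                     length = 655, seed = 1) {
  stopifnot(is.data.frame(species_spec),
            all(c("species", "group") %in% names(species_spec)))
  if (length < 100) stop("sequence length must be >= 100")
  sp <- species_spec$species
  if (anyDuplicated(sp)) stop("duplicated species in species_spec")
  k <- base::length(sp)
  D <- as.matrix(divergence_spec)
  if (!all(sp %in% rownames(D)))
    stop("divergence_spec lacks targets for: ",
         paste(setdiff(sp, rownames(D)), collapse = ", "))
  D <- D[sp, sp, drop = FALSE]
  if (any(D < 0) || any(D > 0.25))
    stop("divergence targets must lie in [0, 0.25]")
  if (any(abs(D - t(D)) > 1e-12)) stop("divergence_spec must be symmetric")

  grp <- setNames(species_spec$group, sp)
  # zero-divergence pairs must be congeners (same group)
  if (k >= 2) {
    for (i in seq_len(k - 1)) for (j in seq(i + 1, k)) {
      if (D[i, j] == 0 && grp[[i]] != grp[[j]])
        stop(sprintf("species %s and %s have divergence target 0 but different group ids",
                     sp[i], sp[j]))
    }
    # triangle inequality, reported with the offending triple
    for (i in seq_len(k)) for (j in seq_len(k)) for (l in seq_len(k)) {
      if (D[i, j] > D[i, l] + D[l, j] + 1e-9)
        stop(sprintf("infeasible divergence spec: d(%s,%s)=%.4f exceeds d(%s,%s)+d(%s,%s)=%.4f",
                     sp[i], sp[j], D[i, j], sp[i], sp[l], sp[l], sp[j],
                     D[i, l] + D[l, j]))
    }
  }

  set.seed(seed)
  bases <- c("A", "C", "G", "T")
  seqs <- setNames(vector("list", k), sp)

  if (k == 1) {
    seqs[[1]] <- sample(bases, length, replace = TRUE)
  } else if (k == 2) {
    s1 <- sample(bases, length, replace = TRUE)
    s2 <- s1
    nm <- round(D[1, 2] * length)
    if (nm > 0) {
      sites <- sample.int(length, nm)
      s2[sites] <- vapply(s1[sites],
                          function(b) sample(setdiff(bases, b), 1), "")
    }
    seqs[[1]] <- s1; seqs[[2]] <- s2
  } else {
    tr <- neighbor_joining(D)
    counts <- round(tr$edge.length * length)
    if (sum(counts) > length)
      stop("infeasible divergence spec: total tree length exceeds sequence length")
    root <- base::length(tr$tip.label) + 1L
    ancestor <- sample(bases, length, replace = TRUE)
    # allocate disjoint site sets to branches, then mutate down the tree
    sites_pool <- sample.int(length, sum(counts))
    offs <- c(0L, cumsum(counts))
    node_seq <- vector("list", base::length(tr$tip.label) + tr$Nnode)
    node_seq[[root]] <- ancestor
    eo <- preorder_edges(tr, root)
    for (e in eo) {
      par <- tr$edge[e, 1]; chd <- tr$edge[e, 2]
      s <- node_seq[[par]]
      if (counts[e] > 0) {
        st <- sites_pool[(offs[e] + 1L):(offs[e] + counts[e])]
        s[st] <- vapply(s[st], function(b) sample(setdiff(bases, b), 1), "")
      }
      node_seq[[chd]] <- s
    }
    for (i in seq_len(base::length(tr$tip.label)))
      seqs[[tr$tip.label[i]]] <- node_seq[[i]]
    seqs <- seqs[sp]
  }

  seq_chr <- vapply(seqs, paste, "", collapse = "")
  panel <- reference_panel(
    data.frame(id = paste0("REF_", sp), species = sp, group = unname(grp[sp]),
               seq = unname(seq_chr), stringsAsFactors = FALSE),
    sister_map = derive_sister_map(D, species_spec)
  )

  # realized distances must honour the targets (catches non-additive specs)
  if (k >= 2) {
    for (i in seq_len(k - 1)) for (j in seq(i + 1, k)) {
      pd <- p_distance(seq_chr[[i]], seq_chr[[j]])
      if (abs(pd - D[i, j]) > 0.005)
        stop(sprintf("divergence spec not realizable (non-additive?): realized d(%s,%s)=%.4f vs target %.4f",
                     sp[i], sp[j], pd, D[i, j]))
    }
  }
  panel
}

# edges of a phylo object in parent-before-child order from `root`
preorder_edges <- function(tr, root) {
  out <- integer(0)
  stack <- which(tr$edge[, 1] == root)
  while (base::length(stack) > 0) {
    e <- stack[1]; stack <- stack[-1]
    out <- c(out, e)
    stack <- c(which(tr$edge[, 1] == tr$edge[e, 2]), stack)
  }
  out
}

# substitute each base independently with probability `rate`
mutate_seq <- function(seq, rate) {
  if (rate <= 0) return(seq)
  ch <- strsplit(seq, "")[[1]]
  hit <- which(runif(base::length(ch)) < rate)
  if (base::length(hit) > 0) {
    bases <- c("A", "C", "G", "T")
    ch[hit] <- vapply(ch[hit], function(b) sample(setdiff(bases, b), 1), "")
  }
  paste(ch, collapse = "")
}

#' Default chimera component partners
#'
#' For a chimeric (mixed-composition) product whose major component belongs to
#' the named group, the contaminant species is drawn from this list. The
#' defaults mirror the mixtures seen in retail surveys: cod products
#' contaminated with haddock or Alaskan pollock, haddock products with cod,
#' and pollock fishcakes with the Vietnamese catfish.
#'
#' @return named list, group id -> candidate contaminant species.
#' @export
default_chimera_partners <- function() {
  list(morhua = c("Melanogrammus_aeglefinus", "Gadus_chalcogrammus"),
       aeglefinus = "Gadus_morhua",
       chalcogramma = "Pangasius_hypophthalmus")
}

# Can a (major, minor) mosaic be flagged by the runner-up rule at the
# smallest minor fraction f? Requires (i) the contaminant group to differ
# from the major's sister group, (ii) enough minor signal to fall below the
# identity threshold, and (iii) the contaminant to outrank the sister as
# runner-up: (1-f) d(maj,sis) + f d(min,sis) > (1-f) d(maj,min) with margin
# for sequencing noise. Undetectable mixtures are planted as replicate
# disagreement instead -- the mode such mixtures surface as in real surveys.
mosaic_detectable <- function(major, minor, panel, f_min, margin = 0.005) {
  if (!major %in% names(panel$sister_map)) return(FALSE)
  sister <- panel$sister_map[[major]]
  rec <- panel$records
  grp <- setNames(rec$group, rec$species)
  if (grp[[minor]] == grp[[sister]]) return(FALSE)
  rs <- function(sp) rec$seq[match(sp, rec$species)]
  d_ms <- p_distance(rs(major), rs(sister))
  d_mm <- p_distance(rs(major), rs(minor))
  d_mins <- p_distance(rs(minor), rs(sister))
  if (f_min * d_mm < 0.008) return(FALSE)
  (1 - f_min) * d_ms + f_min * d_mins - (1 - f_min) * d_mm > margin
}

#' Simulate replicate COI query sequences (including chimeras)
#'
#' Each sample yields two replicate sequences (independent re-extractions).
#' Non-chimeric replicates derive from the true species' reference with
#' independent per-base substitution error. Chimeric samples are simulated in
#' one of two modes, matching the two ways mixtures surface in real data:
#'
#' * `discordant`: the two replicates derive from the two different component
#'   species (replicate disagreement);
#' * `mosaic`: both replicates are copies of one mosaic sequence whose tail
#'   block (20-50% of sites) comes from the contaminant, driving the best-hit
#'   identity below the acceptance threshold with a non-sister runner-up.
#'
#' Mosaic mode is only used where the runner-up rule could in principle flag
#' the mosaic: the contaminant group must differ from the major component's
#' sister group, and the contaminant must outrank the sister as runner-up at
#' the smallest mosaic fraction (with a noise margin). Geometrically
#' undetectable mixtures -- e.g. contamination by the major's own sister
#' group -- are planted as replicate disagreement, the mode such mixtures
#' surface as in real surveys.
#'
#' @param panel a `reference_panel`.
#' @param truth data.frame with `sample_id` and `true_species` (optionally
#'   pre-set `is_chimera`/`chimera_components`).
#' @param seq_error_rate per-base substitution probability.
#' @param chimera_fraction probability a sample is chimeric (if its group has
#'   a partner entry).
#' @param seed integer seed.
#' @param chimera_partners see [default_chimera_partners()].
#' @param mosaic_range range of the contaminant block fraction in mosaic mode.
#' @return list with `queries` (data.frame: query_id, sample_id, replicate,
#'   seq) and the updated `truth` (is_chimera, chimera_components,
#'   chimera_mode filled in).
#' @export
simulate_queries <- function(panel, truth, seq_error_rate = 0.002,
                             chimera_fraction = 0, seed = 1,
                             chimera_partners = default_chimera_partners(),
                             mosaic_range = c(0.2, 0.5)) {
  stopifnot(inherits(panel, "reference_panel"), is.data.frame(truth))
  n <- nrow(truth)
  refs <- setNames(panel$records$seq, panel$records$species)
  grp <- setNames(panel$records$group, panel$records$species)
  missing_sp <- setdiff(truth$true_species, names(refs))
  if (base::length(missing_sp) > 0)
    stop("true species absent from panel: ", paste(missing_sp, collapse = ", "))

  set.seed(seed)
  pre_set <- !is.null(truth$is_chimera)
  if (!pre_set) truth$is_chimera <- FALSE
  if (is.null(truth$chimera_components))
    truth$chimera_components <- vector("list", n)
  truth$chimera_mode <- truth$chimera_mode %||% rep(NA_character_, n)

  for (i in seq_len(n)) {
    g <- grp[[truth$true_species[i]]]
    eligible <- g %in% names(chimera_partners)
    if (pre_set) {
      if (isTRUE(truth$is_chimera[i]) &&
          base::length(truth$chimera_components[[i]]) < 2) {
        if (!eligible)
          stop(sprintf("chimera requested for sample %s with a single component and no partner for group '%s'",
                       truth$sample_id[i], g))
        truth$chimera_components[[i]] <-
          c(truth$true_species[i],
            sample(rep(chimera_partners[[g]], 2), 1))
      }
    } else if (runif(1) < chimera_fraction && eligible) {
      truth$is_chimera[i] <- TRUE
      truth$chimera_components[[i]] <-
        c(truth$true_species[i], sample(rep(chimera_partners[[g]], 2), 1))
    }
    if (truth$is_chimera[i] && is.na(truth$chimera_mode[i])) {
      comp <- truth$chimera_components[[i]]
      truth$chimera_mode[i] <-
        if (mosaic_detectable(comp[1], comp[2], panel, mosaic_range[1]))
          sample(c("discordant", "mosaic"), 1)
        else "discordant"
    }
  }

  qid <- character(2 * n); qsam <- character(2 * n)
  qrep <- integer(2 * n); qseq <- character(2 * n)
  for (i in seq_len(n)) {
    if (truth$is_chimera[i]) {
      comp <- truth$chimera_components[[i]]
      if (truth$chimera_mode[i] == "mosaic") {
        L <- nchar(refs[[comp[1]]])
        f <- runif(1, mosaic_range[1], mosaic_range[2])
        nb <- round(f * L)
        mosaic <- paste0(substr(refs[[comp[1]]], 1, L - nb),
                         substr(refs[[comp[2]]], L - nb + 1, L))
        reps <- c(mutate_seq(mosaic, seq_error_rate),
                  mutate_seq(mosaic, seq_error_rate))
      } else {
        reps <- c(mutate_seq(refs[[comp[1]]], seq_error_rate),
                  mutate_seq(refs[[comp[2]]], seq_error_rate))
      }
    } else {
      r <- refs[[truth$true_species[i]]]
      reps <- c(mutate_seq(r, seq_error_rate), mutate_seq(r, seq_error_rate))
    }
    idx <- (2 * i - 1):(2 * i)
    qid[idx] <- paste0(truth$sample_id[i], "/rep", 1:2)
    qsam[idx] <- truth$sample_id[i]
    qrep[idx] <- 1:2
    qseq[idx] <- reps
  }
  list(queries = data.frame(query_id = qid, sample_id = qsam,
                            replicate = qrep, seq = qseq,
                            stringsAsFactors = FALSE),
       truth = truth)
}

#' Simulate real-time PCR plate fluorescence data
#'
#' Lays samples out on 96-well plates (84 sample wells, 8 no-template
#' controls, 2 positive controls per target species per plate; extra samples
#' spill onto further plates) and simulates 40-cycle dRn trajectories on two
#' dye layers. Wells whose template contains the dye's target species follow a
#' logistic sigmoid `A / (1 + exp(-(cycle - c50)/k))` plus Gaussian noise;
#' all other wells sit at the spectral-bleed offset plus noise.
#'
#' @param samples data.frame with `sample_id`.
#' @param truth data.frame with `sample_id`, `true_species`, `is_chimera`,
#'   `chimera_components` (used to decide which dyes amplify).
#' @param seed integer seed.
#' @param amplification named vector `c(A=, c50=, k=)`.
#' @param ntc_noise_sd per-cycle Gaussian noise sd (fluorescence units).
#' @param bleed_offset constant fluorescence added to non-amplifying wells.
#' @param dye_targets named character, dye -> target species.
#' @return long data.frame: plate_id, well, role, sample_id, dye, cycle,
#'   delta_rn.
#' @export
simulate_plate <- function(samples, truth, seed = 1,
                           amplification = c(A = 3, c50 = 25, k = 1.5),
                           ntc_noise_sd = 0.02, bleed_offset = 0.05,
                           dye_targets = c(COD = "Gadus_morhua",
                                           HAD = "Melanogrammus_aeglefinus")) {
  stopifnot(all(c("A", "c50", "k") %in% names(amplification)))
  set.seed(seed)
  n <- nrow(samples)
  comp <- lapply(seq_len(nrow(truth)), function(i) {
    if (isTRUE(truth$is_chimera[i])) truth$chimera_components[[i]]
    else truth$true_species[i]
  })
  names(comp) <- truth$sample_id

  rows96 <- LETTERS[1:8]
  sample_wells <- paste0(rep(rows96[1:7], each = 12), 1:12)   # A1..G12
  ctrl <- data.frame(
    well = paste0("H", 1:12),
    role = c("POS_COD", "POS_COD", "POS_HAD", "POS_HAD", rep("NTC", 8)),
    stringsAsFactors = FALSE)

  n_plates <- max(1L, ceiling(n / 84))
  wtab <- NULL
  for (p in seq_len(n_plates)) {
    idx <- seq((p - 1) * 84 + 1, min(p * 84, n))
    if (n == 0) idx <- integer(0)
    wt <- rbind(
      if (base::length(idx) > 0)
        data.frame(well = sample_wells[seq_along(idx)], role = "SAMPLE",
                   sample_id = samples$sample_id[idx], stringsAsFactors = FALSE)
      else NULL,
      cbind(ctrl, sample_id = NA_character_))
    wt$plate_id <- sprintf("P%d", p)
    wtab <- rbind(wtab, wt)
  }

  out <- NULL
  A <- amplification[["A"]]; c50 <- amplification[["c50"]]
  kk <- amplification[["k"]]
  sig <- A / (1 + exp(-((1:40) - c50) / kk))
  for (dye in names(dye_targets)) {
    target <- dye_targets[[dye]]
    amp <- vapply(seq_len(nrow(wtab)), function(i) {
      switch(wtab$role[i],
             NTC = FALSE,
             POS_COD = dye == "COD",
             POS_HAD = dye == "HAD",
             SAMPLE = target %in% comp[[wtab$sample_id[i]]])
    }, TRUE)
    base_traj <- ifelse(rep(amp, each = 40), rep(sig, nrow(wtab)),
                        bleed_offset)
    d <- data.frame(
      plate_id = rep(wtab$plate_id, each = 40),
      well = rep(wtab$well, each = 40),
      role = rep(wtab$role, each = 40),
      sample_id = rep(wtab$sample_id, each = 40),
      dye = dye,
      cycle = rep(1:40, nrow(wtab)),
      delta_rn = base_traj + rnorm(40 * nrow(wtab), 0, ntc_noise_sd),
      stringsAsFactors = FALSE)
    out <- rbind(out, d)
  }
  out <- out[order(out$plate_id, out$well, out$dye, out$cycle), ]
  rownames(out) <- NULL
  out
}

#' Simulation configuration for a synthetic labelling survey
#'
#' Defaults emulate a 371-sample UK supermarket whitefish survey: label mix
#' cod 179 (57 Atlantic, 20 Pacific, 102 unspecified), haddock 155, Alaskan
#' pollack 32, hake 4, whiting 1; processing levels 84/84/31/128/44
#' (fresh/frozen fillet, battered/breaded fillet, fish finger, pre-cooked
#' meal, fishcake); planted substitutions and chimeras totalling an expected
#' mislabelling rate of 21/371 = 5.66%.
#'
#' @param seed master seed (child streams are derived deterministically).
#' @param n_samples number of retail samples.
#' @param label_distribution data.frame: label, area, prop, true_species.
#' @param mislabel_matrix data.frame: label, area, substitute, prob -- the
#'   probability a product with that label carries the substitute species.
#' @param chimera_fraction probability a sample is a mixed-composition
#'   product.
#' @param seq_error_rate per-base sequencing error.
#' @param amplification sigmoid parameters `c(A=, c50=, k=)`, `A >= 0`,
#'   `c50` in `[1, 40]`, `k > 0`.
#' @param ntc_noise_sd,bleed_offset fluorescence noise model (units of dRn).
#' @param processing_level_distribution proportions for levels 1-5.
#' @param seq_length COI amplicon length.
#' @param chimera_partners,mosaic_range see [simulate_queries()].
#' @return object of class `sim_config`.
#' @export
sim_config <- function(seed = 1,
                       n_samples = 371,
                       label_distribution = default_label_distribution(),
                       mislabel_matrix = default_mislabel_matrix(),
                       chimera_fraction = 5 / 371,
                       seq_error_rate = 0.002,
                       amplification = c(A = 3, c50 = 25, k = 1.5),
                       ntc_noise_sd = 0.02,
                       bleed_offset = 0.05,
                       processing_level_distribution =
                         c(84, 84, 31, 128, 44) / 371,
                       seq_length = 655,
                       chimera_partners = default_chimera_partners(),
                       mosaic_range = c(0.2, 0.5)) {
  stopifnot(n_samples >= 0)
  if (abs(sum(label_distribution$prop) - 1) > 1e-9)
    stop("label_distribution proportions must sum to 1")
  if (abs(sum(processing_level_distribution) - 1) > 1e-9)
    stop("processing_level_distribution must sum to 1")
  if (any(mislabel_matrix$prob < 0 | mislabel_matrix$prob > 1))
    stop("mislabel probabilities must lie in [0, 1]")
  if (chimera_fraction < 0 || chimera_fraction > 1)
    stop("chimera_fraction must lie in [0, 1]")
  stopifnot(all(c("A", "c50", "k") %in% names(amplification)),
            amplification[["A"]] >= 0,
            amplification[["c50"]] >= 1, amplification[["c50"]] <= 40,
            amplification[["k"]] > 0)
  structure(list(seed = seed, n_samples = n_samples,
                 label_distribution = label_distribution,
                 mislabel_matrix = mislabel_matrix,
                 chimera_fraction = chimera_fraction,
                 seq_error_rate = seq_error_rate,
                 amplification = amplification,
                 ntc_noise_sd = ntc_noise_sd, bleed_offset = bleed_offset,
                 processing_level_distribution = processing_level_distribution,
                 seq_length = seq_length,
                 chimera_partners = chimera_partners,
                 mosaic_range = mosaic_range),
            class = "sim_config")
}

#' @rdname sim_config
#' @export
default_label_distribution <- function() {
  data.frame(
    label = c("Cod", "Cod", "Cod", "Haddock", "Alaskan Pollack",
              "Hake (M. capensis)", "Whiting"),
    area = c("Atlantic", "Pacific", NA, "Atlantic", "Pacific", NA, NA),
    prop = c(57, 20, 102, 155, 32, 4, 1) / 371,
    true_species = c("Gadus_morhua", "Gadus_macrocephalus", "Gadus_morhua",
                     "Melanogrammus_aeglefinus", "Gadus_chalcogrammus",
                     "Merluccius_capensis", "Merlangius_merlangus"),
    stringsAsFactors = FALSE
  )
}

#' @rdname sim_config
#' @export
default_mislabel_matrix <- function() {
  data.frame(
    label = c("Cod", "Cod", "Haddock", "Haddock",
              "Hake (M. capensis)", "Whiting"),
    area = c("Atlantic", NA, "Atlantic", "Atlantic", NA, NA),
    substitute = c("Gadus_macrocephalus", "Melanogrammus_aeglefinus",
                   "Gadus_morhua", "Gadus_macrocephalus",
                   "Merluccius_paradoxus", "Micromesistius_poutassou"),
    prob = c(6 / 57, 1 / 102, 6 / 155, 1 / 155, 1 / 4, 1),
    stringsAsFactors = FALSE
  )
}

#' Simulate a complete synthetic labelling survey
#'
#' End-to-end harness: reference panel, sample metadata with planted
#' mislabelling, replicate query sequences (with chimeras) and plate
#' fluorescence. All cross-references (sample to wells to sequences) resolve,
#' and identical config + seed give byte-identical output.
#'
#' @param config a [sim_config()].
#' @return object of class `fish_study`: list with `samples`, `truth`,
#'   `queries`, `plates`, `panel`, `config`.
#' @export
simulate_study <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_samples
  seeds <- child_seeds(config$seed, 4)
  panel <- simulate_reference_panel(length = config$seq_length,
                                    seed = seeds[1])

  if (n == 0) {
    empty_truth <- data.frame(sample_id = character(0),
                              label_species = character(0),
                              catch_area = character(0),
                              processing_level = integer(0),
                              true_species = character(0),
                              is_chimera = logical(0),
                              planted_mislabel = logical(0))
    return(structure(list(samples = empty_truth[, 1:4], truth = empty_truth,
                          queries = data.frame(query_id = character(0),
                                               sample_id = character(0),
                                               replicate = integer(0),
                                               seq = character(0)),
                          plates = simulate_plate(empty_truth, empty_truth,
                                                  seed = seeds[4],
                                                  amplification = config$amplification,
                                                  ntc_noise_sd = config$ntc_noise_sd,
                                                  bleed_offset = config$bleed_offset),
                          panel = panel, config = config),
                     class = "fish_study"))
  }

  set.seed(seeds[2])
  # deterministic label-class counts (largest remainder), shuffled order
  ld <- config$label_distribution
  cnt <- floor(ld$prop * n)
  rem <- n - sum(cnt)
  if (rem > 0) {
    frac <- ld$prop * n - cnt
    cnt[order(-frac)[seq_len(rem)]] <- cnt[order(-frac)[seq_len(rem)]] + 1L
  }
  cls <- sample(rep(seq_len(nrow(ld)), cnt))
  lvl_cnt <- floor(config$processing_level_distribution * n)
  lrem <- n - sum(lvl_cnt)
  if (lrem > 0) {
    lfrac <- config$processing_level_distribution * n - lvl_cnt
    lvl_cnt[order(-lfrac)[seq_len(lrem)]] <-
      lvl_cnt[order(-lfrac)[seq_len(lrem)]] + 1L
  }
  lvl <- sample(rep(1:5, lvl_cnt))

  truth <- data.frame(
    sample_id = sprintf("S%04d", seq_len(n)),
    label_species = ld$label[cls],
    catch_area = ld$area[cls],
    processing_level = lvl,
    true_species = ld$true_species[cls],
    stringsAsFactors = FALSE
  )

  # plant substitutions: P(substitute_j | not chimera) = p_j / (1 - cf),
  # so the marginal substitution probability equals the configured p_j
  cf <- config$chimera_fraction
  mm <- config$mislabel_matrix
  for (i in seq_len(n)) {
    rows <- mm[mm$label == truth$label_species[i] &
                 (is.na(mm$area) == is.na(truth$catch_area[i])) &
                 (is.na(mm$area) | mm$area %in% truth$catch_area[i]), ,
               drop = FALSE]
    if (nrow(rows) == 0) next
    q <- pmin(rows$prob / max(1 - cf, 1e-12), 1)
    if (sum(q) > 1) q <- q / sum(q)
    u <- runif(1)
    cq <- cumsum(q)
    hit <- which(u < cq)
    if (base::length(hit) > 0)
      truth$true_species[i] <- rows$substitute[hit[1]]
  }

  qs <- simulate_queries(panel, truth,
                         seq_error_rate = config$seq_error_rate,
                         chimera_fraction = cf, seed = seeds[3],
                         chimera_partners = config$chimera_partners,
                         mosaic_range = config$mosaic_range)
  truth <- qs$truth

  grp <- setNames(panel$records$group, panel$records$species)
  rules <- congruence_rules()
  congruent <- vapply(seq_len(n), function(i) {
    allowed <- allowed_groups(truth$label_species[i], truth$catch_area[i],
                              rules)
    grp[[truth$true_species[i]]] %in% allowed
  }, TRUE)
  truth$planted_mislabel <- truth$is_chimera | !congruent

  samples <- truth[, c("sample_id", "label_species", "catch_area",
                       "processing_level")]
  plates <- simulate_plate(samples, truth, seed = seeds[4],
                           amplification = config$amplification,
                           ntc_noise_sd = config$ntc_noise_sd,
                           bleed_offset = config$bleed_offset)
  structure(list(samples = samples, truth = truth, queries = qs$queries,
                 plates = plates, panel = panel, config = config),
            class = "fish_study")
}

#' @export
print.fish_study <- function(x, ...) {
  cat("Synthetic labelling survey:", nrow(x$samples), "samples,",
      nrow(x$queries), "query sequences,",
      base::length(unique(x$plates$plate_id)), "plates\n")
  if (nrow(x$truth) > 0)
    cat(sprintf("Planted mislabelling: %d/%d (%.2f%%), %d chimeric\n",
                sum(x$truth$planted_mislabel), nrow(x$truth),
                100 * mean(x$truth$planted_mislabel),
                sum(x$truth$is_chimera)))
  invisible(x)
}
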