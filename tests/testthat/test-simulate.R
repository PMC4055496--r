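test_that("reference panels hit their divergence targets", {
  # target 0 -> byte-identical congeners
  spec <- data.frame(species = c("A_sp", "B_sp"), group = c("g1", "g1"))
  D <- matrix(0, 2, 2, dimnames = list(spec$species, spec$species))
  p0 <- simulate_reference_panel(spec, D, length = 655, seed = 1)
  expect_identical(p0$records$seq[1], p0$records$seq[2])
  expect_equal(pairwise_identity(align_pair(p0$records$seq[1],
                                            p0$records$seq[2])), 1)

  # target 0.02 over 655 bases -> about 13 differing sites
  spec2 <- data.frame(species = c("A_sp", "B_sp"), group = c("g1", "g2"))
  D2 <- matrix(c(0, 0.02, 0.02, 0), 2, 2,
               dimnames = list(spec2$species, spec2$species))
  p2 <- simulate_reference_panel(spec2, D2, length = 655, seed = 2)
  mm <- sum(strsplit(p2$records$seq[1], "")[[1]] !=
              strsplit(p2$records$seq[2], "")[[1]])
  expect_lte(abs(mm - 0.02 * 655), 3)

  # the default gadoid panel: all cross-group identities < 0.98
  p <- simulate_reference_panel(seed = 4)
  rec <- p$records
  for (i in seq_len(nrow(rec) - 1)) for (j in seq(i + 1, nrow(rec))) {
    id <- 1 - p_distance(rec$seq[i], rec$seq[j])
    if (rec$group[i] == rec$group[j]) expect_equal(id, 1)
    else expect_lt(id, 0.98)
  }
  # realized distances match targets within 0.005
  D <- default_divergences()
  for (i in seq_len(nrow(rec) - 1)) for (j in seq(i + 1, nrow(rec))) {
    expect_lte(abs(p_distance(rec$seq[i], rec$seq[j]) -
                     D[rec$species[i], rec$species[j]]), 0.005)
  }
})

test_that("panel generation is deterministic and rejects bad specs", {
  pa <- simulate_reference_panel(seed = 9)
  pb <- simulate_reference_panel(seed = 9)
  expect_identical(pa$records, pb$records)

  # zero divergence across groups is contradictory
  spec <- data.frame(species = c("A_sp", "B_sp"), group = c("g1", "g2"))
  D0 <- matrix(0, 2, 2, dimnames = list(spec$species, spec$species))
  expect_error(simulate_reference_panel(spec, D0, seed = 1),
               "different group")

  # triangle violation is reported with the offending triple
  spec3 <- data.frame(species = c("A_sp", "B_sp", "C_sp"),
                      group = c("g1", "g2", "g3"))
  D3 <- matrix(c(0, 0.2, 0.02, 0.2, 0, 0.02, 0.02, 0.02, 0), 3, 3,
               dimnames = list(spec3$species, spec3$species))
  expect_error(simulate_reference_panel(spec3, D3, seed = 1),
               "infeasible.*A_sp.*B_sp")
})

test_that("replicate queries carry the configured error rate", {
  panel <- simulate_reference_panel(seed = 6)
  truth <- data.frame(sample_id = sprintf("S%03d", 1:500),
                      true_species = "Gadus_morhua",
                      stringsAsFactors = FALSE)
  # zero error -> byte-identical to the reference
  q0 <- simulate_queries(panel, truth[1:3, , drop = FALSE],
                         seq_error_rate = 0, seed = 1)
  ref <- panel$records$seq[panel$records$species == "Gadus_morhua"]
  expect_true(all(q0$queries$seq == ref))

  # error 0.002 on 655 bases -> mean 1.31 mismatches per replicate
  qs <- simulate_queries(panel, truth, seq_error_rate = 0.002, seed = 2)
  rc <- strsplit(ref, "")[[1]]
  mm <- vapply(qs$queries$seq, function(s)
    sum(strsplit(s, "")[[1]] != rc), 0)
  expect_lte(abs(mean(mm) - 655 * 0.002), 0.2)

  # a pre-declared chimera with a single listed component and no partner
  tbad <- data.frame(sample_id = "S1", true_species = "Merlangius_merlangus",
                     is_chimera = TRUE, stringsAsFactors = FALSE)
  tbad$chimera_components <- list(character(0))
  expect_error(simulate_queries(panel, tbad, seed = 1),
               "single component")
})

test_that("chimeric samples reconcile as MIXED through the pipeline", {
  panel <- simulate_reference_panel(seed = 6)
  truth <- data.frame(sample_id = sprintf("C%03d", 1:20),
                      true_species = rep(c("Gadus_morhua",
                                           "Melanogrammus_aeglefinus"), 10),
                      is_chimera = TRUE, stringsAsFactors = FALSE)
  qs <- simulate_queries(panel, truth, seq_error_rate = 0.002,
                         chimera_fraction = 1, seed = 8)
  hits <- 0
  for (sid in truth$sample_id) {
    reps <- qs$queries[qs$queries$sample_id == sid, ]
    a1 <- assign_species(reps$seq[1], panel)
    a2 <- assign_species(reps$seq[2], panel)
    r <- reconcile_replicates(a1, a2,
                              mixed_flags = c(detect_mixed(a1, panel),
                                              detect_mixed(a2, panel)))
    hits <- hits + r$mixed
  }
  expect_equal(hits, 20)
})

test_that("plate fluorescence follows the sigmoid/noise model", {
  st <- simulate_study(sim_config(seed = 31, n_samples = 50))
  pl <- st$plates
  tr <- st$truth
  # a cod-template well on the cod dye plateaus near A (>= A/2)
  cod_ids <- tr$sample_id[tr$true_species == "Gadus_morhua" & !tr$is_chimera]
  w <- pl[pl$sample_id %in% cod_ids & pl$dye == "COD" & pl$cycle == 40, ]
  expect_true(all(w$delta_rn >= 3 / 2))
  # NTC endpoints stay within 4 sd of the bleed offset
  ntc <- pl[pl$role == "NTC" & pl$cycle == 40, ]
  expect_true(all(abs(ntc$delta_rn - 0.05) <= 4 * 0.02))
  # determinism
  st2 <- simulate_study(sim_config(seed = 31, n_samples = 50))
  expect_identical(st$plates, st2$plates)
  expect_identical(st$queries, st2$queries)
})

test_that("studies are internally consistent and degenerate inputs work", {
  st <- simulate_study(sim_config(seed = 13, n_samples = 100))
  # cross-references resolve: every sample has 2 replicates and a well per dye
  expect_equal(sort(unique(st$queries$sample_id)), sort(st$samples$sample_id))
  expect_true(all(table(st$queries$sample_id) == 2))
  sw <- unique(st$plates[st$plates$role == "SAMPLE",
                         c("sample_id", "well", "plate_id")])
  expect_equal(sort(sw$sample_id), sort(st$samples$sample_id))

  # n = 0: empty outputs, no error
  st0 <- simulate_study(sim_config(seed = 1, n_samples = 0))
  expect_equal(nrow(st0$samples), 0)
  expect_equal(nrow(st0$queries), 0)

  # an empty mislabel matrix and no chimeras -> pipeline estimate exactly 0
  cfg <- sim_config(seed = 5, n_samples = 40,
                    mislabel_matrix = default_mislabel_matrix()[0, ],
                    chimera_fraction = 0)
  stc <- simulate_study(cfg)
  expect_equal(sum(stc$truth$planted_mislabel), 0)
  res <- audit_study(stc)
  expect_equal(res$summary$overall$k, 0)
})

test_that("planted mislabelling is unbiased for the configured rate", {
  rates <- vapply(1:30, function(s)
    mean(simulate_study(sim_config(seed = 600 + s))$truth$planted_mislabel),
    0)
  mc_se <- sd(rates) / sqrt(length(rates))
  expect_lte(abs(mean(rates) - 21 / 371), 2 * mc_se)
})

test_that("configuration validation catches inconsistent inputs", {
  expect_error(sim_config(label_distribution = within(
    default_label_distribution(), prop <- prop * 0.9)), "sum to 1")
  mm <- default_mislabel_matrix(); mm$prob[1] <- 1.2
  expect_error(sim_config(mislabel_matrix = mm), "\\[0, 1\\]")
  expect_error(sim_config(chimera_fraction = -0.1), "chimera_fraction")
  expect_error(sim_config(amplification = c(A = 3, c50 = 60, k = 1.5)))
})
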