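test_that("alignment scores match an exhaustive enumeration oracle", {
  expect_equal(align_pair("ACGT", "ACGT")$score, 4)
  expect_equal(align_pair("ACGT", "ACGA")$score, 2)
  a <- align_pair("ACGTACGT", "ACGACGT")
  expect_equal(a$score, brute_semiglobal_score("ACGTACGT", "ACGACGT"))
  expect_equal(nchar(a$aligned_a), nchar(a$aligned_b))

  set.seed(42)
  for (i in 1:30) {
    x <- random_seq(sample(3:7, 1), bases = c("A", "C", "G", "T", "N"))
    y <- random_seq(sample(3:7, 1), bases = c("A", "C", "G", "T", "N"))
    expect_equal(align_pair(x, y)$score, brute_semiglobal_score(x, y),
                 info = paste(x, y))
  }
  expect_error(align_pair("ACGT", "ACXT"), "non-IUPAC")
})

test_that("identity excludes terminal gaps and counts internal gaps against", {
  set.seed(7)
  s <- random_seq(655)
  expect_equal(pairwise_identity(align_pair(s, s)), 1)
  s1 <- substitute_sites(s, 1, interior = TRUE)
  expect_equal(pairwise_identity(align_pair(s, s1)), 654 / 655)
  # a terminal overhang is excluded from the denominator
  a <- align_pair(s, substr(s, 11, 655))
  expect_equal(pairwise_identity(a), 1)
  # the R identity equals the C++ path identity (matches/columns)
  for (i in 1:10) {
    x <- substitute_sites(s, sample(0:40, 1))
    al <- align_pair(s, x)
    expect_equal(pairwise_identity(al), al$matches / al$columns)
  }
})

test_that("identity is symmetric, bounded, and 1 only for identical pairs", {
  set.seed(12)
  for (i in 1:15) {
    x <- random_seq(200)
    y <- substitute_sites(x, sample(0:30, 1), interior = TRUE)
    ixy <- pairwise_identity(align_pair(x, y))
    iyx <- pairwise_identity(align_pair(y, x))
    expect_equal(ixy, iyx)
    expect_gte(ixy, 0); expect_lte(ixy, 1)
    expect_equal(ixy == 1, x == y)
  }
})

test_that("species assignment agrees with a brute-force per-pair scan", {
  set.seed(31)
  for (rep in 1:5) {
    len <- 300
    base <- random_seq(len)
    nref <- sample(5:12, 1)
    refs <- vapply(seq_len(nref), function(i)
      substitute_sites(base, sample(5:35, 1), interior = TRUE), "")
    panel <- reference_panel(data.frame(
      id = sprintf("r%02d", 1:nref),
      species = sprintf("Sp_%02d", 1:nref),
      group = sprintf("g%02d", 1:nref),
      seq = refs, stringsAsFactors = FALSE))
    for (k in 1:10) {
      true_i <- sample(nref, 1)
      q <- substitute_sites(refs[true_i], sample(0:3, 1), interior = TRUE)
      ora_id <- vapply(refs, function(r)
        pairwise_identity(align_pair(q, r)), 0)
      a <- assign_species(q, panel)
      best <- max(ora_id)
      expect_equal(a$best_identity, best)
      tied_groups <- sort(unique(panel$records$group[ora_id == best]))
      expect_equal(a$best_group, tied_groups)
      out <- which(!(panel$records$group %in% tied_groups))
      expect_equal(a$runner_up_identity, max(ora_id[out]))
      expect_equal(a$status,
                   if (best < 0.995) "BELOW_THRESHOLD"
                   else if (length(tied_groups) > 1) "AMBIGUOUS_GROUP"
                   else "UNAMBIGUOUS")
    }
  }
})

test_that("congener ties stay unambiguous at group level; cross-group ties do not", {
  p <- toy_panel()
  recs <- p$records
  # query identical to both congeners (same group, identical sequences)
  a <- assign_species(recs$seq[1], p)
  expect_equal(a$status, "UNAMBIGUOUS")
  expect_equal(a$best_group, "alpha")
  expect_equal(a$best_identity, 1)
  # query exactly between alpha and beta: flip half the alpha/beta diffs
  set.seed(5)
  ca <- strsplit(recs$seq[1], "")[[1]]; cb <- strsplit(recs$seq[3], "")[[1]]
  diffs <- which(ca != cb)
  stopifnot(length(diffs) %% 2 == 0)
  q <- ca; flip <- diffs[seq_len(length(diffs) / 2)]
  q[flip] <- cb[flip]
  a2 <- assign_species(paste(q, collapse = ""), p, threshold = 0.5)
  expect_equal(a2$status, "AMBIGUOUS_GROUP")
  expect_equal(a2$best_group, c("alpha", "beta"))
})

test_that("queries are matched in either orientation", {
  p <- toy_panel()
  q <- substitute_sites(p$records$seq[3], 2)
  fwd <- assign_species(q, p)
  rev <- assign_species(revcomp_chr(q), p)
  expect_equal(fwd$best_identity, rev$best_identity)
  expect_equal(fwd$best_group, rev$best_group)
  expect_equal(rev$orientation, -1L)
})

test_that("mixture flagging follows the sub-threshold non-sister rule", {
  set.seed(88)
  panel <- simulate_reference_panel(seed = 3)
  rec <- panel$records
  rs <- function(sp) rec$seq[rec$species == sp]
  # mosaic: 75% haddock + 25% cod -> sub-threshold haddock with cod runner-up
  L <- nchar(rs("Melanogrammus_aeglefinus"))
  nb <- round(0.25 * L)
  mosaic <- paste0(substr(rs("Melanogrammus_aeglefinus"), 1, L - nb),
                   substr(rs("Gadus_morhua"), L - nb + 1, L))
  a <- assign_species(mosaic, panel)
  expect_equal(a$status, "BELOW_THRESHOLD")
  expect_equal(a$best_species, "Melanogrammus_aeglefinus")
  expect_equal(a$runner_up_species, "Gadus_morhua")
  expect_true(detect_mixed(a, panel))

  # at or above threshold the flag is FALSE regardless of runner-up
  clean <- rs("Melanogrammus_aeglefinus")
  a2 <- assign_species(clean, panel)
  expect_equal(a2$status, "UNAMBIGUOUS")
  expect_false(detect_mixed(a2, panel))

  # sub-threshold with sister-consistent runner-up: plain divergence, no flag
  noisy <- substitute_sites(rs("Melanogrammus_aeglefinus"), 6)
  a3 <- assign_species(noisy, panel)
  expect_equal(a3$status, "BELOW_THRESHOLD")
  expect_equal(a3$runner_up_species, panel$sister_map[["Melanogrammus_aeglefinus"]])
  expect_false(detect_mixed(a3, panel))

  # species missing from the sister map errors
  p2 <- panel; p2$sister_map <- p2$sister_map[
    names(p2$sister_map) != "Melanogrammus_aeglefinus"]
  expect_error(detect_mixed(a, p2), "sister map")
})

test_that("replicate reconciliation covers agreement, disagreement and flags", {
  p <- simulate_reference_panel(seed = 3)
  rs <- function(sp) p$records$seq[p$records$species == sp]
  amor <- assign_species(rs("Gadus_morhua"), p)
  ahad <- assign_species(rs("Melanogrammus_aeglefinus"), p)
  amac <- assign_species(rs("Gadus_macrocephalus"), p)

  r <- reconcile_replicates(amor, ahad, sample_id = "x")
  expect_true(r$mixed)
  expect_equal(r$final, c("aeglefinus", "morhua"))

  r2 <- reconcile_replicates(amac, amac)
  expect_false(r2$mixed)
  expect_equal(r2$final, "macrocephalus")

  # any group with itself reconciles to itself
  for (a in list(amor, ahad, amac)) {
    ri <- reconcile_replicates(a, a)
    expect_false(ri$mixed)
    expect_equal(ri$final, a$best_group)
  }

  # a mixture flag forces MIXED(best + runner-up groups)
  L <- nchar(rs("Melanogrammus_aeglefinus"))
  nb <- round(0.25 * L)
  mosaic <- paste0(substr(rs("Melanogrammus_aeglefinus"), 1, L - nb),
                   substr(rs("Gadus_morhua"), L - nb + 1, L))
  am <- assign_species(mosaic, p)
  rf <- reconcile_replicates(am, am, mixed_flags = c(TRUE, TRUE))
  expect_true(rf$mixed)
  expect_equal(rf$final, c("aeglefinus", "morhua"))

  # missing replicates
  r1 <- reconcile_replicates(amor, NULL)
  expect_equal(r1$final, "morhua")
  expect_true(r1$single_replicate)
  r0 <- reconcile_replicates(NULL, NULL)
  expect_equal(r0$final, "UNRESOLVED")

  # plain group labels (transcribed identifications) work too
  rt <- reconcile_replicates("morhua", "aeglefinus")
  expect_true(rt$mixed)
  expect_equal(rt$final, c("aeglefinus", "morhua"))
})

test_that("panel FASTA round-trips through the header convention", {
  p <- simulate_reference_panel(seed = 5)
  f <- tempfile(fileext = ".fasta")
  write_panel_fasta(p, f)
  p2 <- read_panel_fasta(f)
  expect_equal(p2$records$species, p$records$species)
  expect_equal(p2$records$group, p$records$group)
  expect_equal(p2$records$seq, p$records$seq)
})
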