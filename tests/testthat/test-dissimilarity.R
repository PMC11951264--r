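test_that("Bray-Curtis matches its defining formula", {
  expect_equal(bray_curtis(c(2, 0, 4), c(2, 0, 4)), 0)
  expect_equal(bray_curtis(c(3, 0), c(0, 5)), 1)
  expect_equal(bray_curtis(c(2, 0, 4), c(0, 2, 4)), 1 / 3)
  expect_error(bray_curtis(c(0, 0), c(0, 0)),
               class = "hfa_undefined_ratio_error")
  expect_error(bray_curtis(c(1, 2), c(1, 2, 3)), class = "hfa_value_error")
})

test_that("Bray-Curtis agrees with a naive loop and with vegan", {
  skip_if_not_installed("vegan")
  set.seed(11)
  for (i in 1:100) {
    u <- rpois(20, 5); v <- rpois(20, 5)
    if (sum(u) + sum(v) == 0) next
    expect_equal(bray_curtis(u, v), oracle_bray_curtis(u, v),
                 tolerance = 1e-12)
  }
  m <- matrix(rpois(60, 8), nrow = 10,
              dimnames = list(paste0("t", 1:10), paste0("s", 1:6)))
  d <- bray_curtis_matrix(m)
  dv <- as.matrix(vegan::vegdist(t(m), method = "bray"))
  expect_equal(unname(d), unname(dv), tolerance = 1e-12)
})

test_that("dissimilarity abundance is a symmetric non-negative log-ratio", {
  expect_equal(dissimilarity_abundance(0.2, 0.05), 2)
  expect_equal(dissimilarity_abundance(0.05, 0.2), 2)
  for (x in c(0.01, 0.3, 0.9))
    expect_equal(dissimilarity_abundance(x, x), 0)
  expect_error(dissimilarity_abundance(0, 0, pseudocount = 0),
               class = "hfa_undefined_ratio_error")
  set.seed(12)
  a <- runif(100); b <- runif(100)
  da <- dissimilarity_abundance(a, b, 0.001)
  expect_equal(da, dissimilarity_abundance(b, a, 0.001))
  expect_true(all(da >= 0))
})

test_that("home/away pairing mirrors the mean-HFA contrast", {
  u <- expand_design(one_harvest_design())
  p <- pair_samples(u)
  expect_equal(nrow(p), 8L)  # 2 species x 4 replicates
  # every home sample is the species' litter in its own soil
  home_units <- u[match(p$home_sample, u$unit_id), ]
  expect_true(all(home_units$is_home))
  expect_equal(home_units$litter_species, p$species)
  # litter-fixed contrast: away partner keeps the litter, changes the soil
  away_units <- u[match(p$away_sample, u$unit_id), ]
  expect_equal(away_units$litter_species, p$species)
  expect_true(all(!away_units$is_home))

  u1 <- expand_design(one_harvest_design(replicates = 1L))
  expect_equal(nrow(pair_samples(u1)), 2L)

  # site-fixed alternative holds the soil and varies the litter
  ps <- pair_samples(u, contrast = "site_fixed")
  away_units <- u[match(ps$away_sample, u$unit_id), ]
  expect_equal(away_units$soil_source, ps$species)

  err <- expect_error(pair_samples(u[u$unit_id != "P_C_m4_2", ]),
                      class = "hfa_incomplete_design_error")
  expect_match(conditionMessage(err), "litter P in soil C")
})

test_that("dissimilarity table matches a spreadsheet-style recomputation", {
  # hand-built pair of communities over 3 classes, 6 OTUs
  counts <- matrix(c(40L, 20L,
                     20L, 10L,
                     20L, 40L,
                     10L,  5L,
                     10L, 25L,
                      0L,  0L),
                   nrow = 6, byrow = TRUE,
                   dimnames = list(paste0("OTU", 1:6), c("P_P_m4_1", "P_C_m4_1")))
  tax <- data.frame(otu_id = paste0("OTU", 1:6),
                    class = c("Sordariomycetes", "Sordariomycetes",
                              "Eurotiomycetes", "Eurotiomycetes",
                              "Tremellomycetes", "Tremellomycetes"),
                    genus = paste0("g", 1:6), stringsAsFactors = FALSE)
  tab <- otu_table(counts, tax)
  pairs <- data.frame(species = "P", harvest_id = "m4", month = 4,
                      treatment = "CK", replicate = 1,
                      home_sample = "P_P_m4_1", away_sample = "P_C_m4_1",
                      stringsAsFactors = FALSE)
  res <- dissimilarity_table(tab, pairs,
                             dominant = c("Sordariomycetes", "Eurotiomycetes",
                                          "Tremellomycetes"),
                             pseudocount = 0)
  # Bray-Curtis by hand: totals 100 each; min sums = 20+10+20+5+10 = 65
  expect_equal(res$bray_curtis, 1 - 2 * 65 / 200)
  # class shares home (.6,.3,.1) vs away (.3,.45,.25)
  expect_equal(res$dis_Sordariomycetes, abs(log2(0.6 / 0.3)))
  expect_equal(res$dis_Eurotiomycetes, abs(log2(0.3 / 0.45)))
  expect_equal(res$dis_Tremellomycetes, abs(log2(0.1 / 0.25)))

  # identical home/away communities: everything zero
  counts2 <- counts; counts2[, 2] <- counts2[, 1]
  tab2 <- otu_table(counts2, tax)
  res2 <- dissimilarity_table(tab2, pairs,
                              dominant = "Sordariomycetes", pseudocount = 0)
  expect_equal(res2$bray_curtis, 0)
  expect_equal(res2$dis_Sordariomycetes, 0)

  # one class doubled with a near-zero pseudocount scores ~1 bit
  expect_equal(dissimilarity_abundance(0.6, 0.3, 1e-9), 1, tolerance = 1e-6)
})

test_that("without a source effect, home/away dissimilarity hits the baseline", {
  # when soil sources share one community distribution, paired home/away
  # Bray-Curtis should match the within-source level (pure sampling noise)
  d <- one_harvest_design()
  u <- expand_design(d)
  m0 <- community_model(source_effect = 0, succession_slope = 0,
                        glucose_shift = 0)
  gap <- vapply(1:30, function(s) {
    ot <- simulate_communities(d, m0, seed = 900 + s)
    pairs <- pair_samples(u)
    across <- mapply(function(h, a) bray_curtis(ot$counts[, h], ot$counts[, a]),
                     pairs$home_sample, pairs$away_sample)
    # within-source baseline: replicate pairs inside each (litter, soil) cell
    cells <- split(u$unit_id, paste(u$litter_species, u$soil_source))
    within <- unlist(lapply(cells, function(ids)
      vapply(seq_len(length(ids) - 1), function(i)
        bray_curtis(ot$counts[, ids[i]], ot$counts[, ids[i + 1]]),
        numeric(1))))
    mean(across) - mean(within)
  }, numeric(1))
  expect_lt(abs(mean(gap)), 0.02)
})
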