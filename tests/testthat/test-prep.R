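test_that("quality filter keeps clean reads and truncates at the failing window", {
  params <- filter_params()
  clean <- simulate_reads(3, length = 350, base_quality = 40, quality_sd = 0,
                          seed = 1)
  out <- quality_filter(clean, params)
  expect_equal(nrow(out$reads), 3L)
  expect_equal(nchar(out$reads$seq), rep(350L, 3))

  # 40 bp of Q40 then Q10: every window touching the Q10 block fails, so the
  # oracle truncation lands before 90 bp and the remnant is under 50 bp
  q <- c(rep(40L, 40), rep(10L, 310))
  read <- data.frame(id = "r1",
                     seq = paste(rep("A", 350), collapse = ""),
                     qual = intToUtf8(q + 33L), stringsAsFactors = FALSE)
  len <- oracle_truncation(q, 50, 20)
  expect_lt(len, 90)
  out <- quality_filter(read, params)
  expect_equal(out$log$disposition, "short")
  expect_equal(out$log$kept_length, len)

  # ambiguous characters are discarded outright
  nread <- data.frame(id = "r2",
                      seq = paste(c(rep("A", 100), "N", rep("A", 249)),
                                  collapse = ""),
                      qual = intToUtf8(rep(73L, 350)),
                      stringsAsFactors = FALSE)
  expect_equal(quality_filter(nread, params)$log$disposition, "ambiguous")

  bad <- data.frame(id = "r3", seq = "ACGT", qual = "III",
                    stringsAsFactors = FALSE)
  expect_error(quality_filter(bad, params), class = "hfa_format_error")
})

test_that("quality filter agrees with the brute-force window oracle", {
  reads <- simulate_reads(1000, length = 200, base_quality = 24,
                          quality_sd = 6, seed = 7)
  reads2 <- simulate_reads(1000, length = 200, base_quality = 30,
                           quality_sd = 3, dip_start = 120, dip_quality = 12,
                           seed = 8)
  reads <- rbind(reads, reads2)
  out <- quality_filter(reads, filter_params())
  for (i in seq_len(nrow(reads))) {
    q <- utf8ToInt(reads$qual[i]) - 33L
    len <- oracle_truncation(q, 50, 20)
    expect_equal(out$log$kept_length[i],
                 if (len < 50) out$log$kept_length[i] else len)
    expect_equal(out$log$disposition[i] == "kept", len >= 50)
    if (len >= 50) expect_equal(out$log$kept_length[i], len)
  }
})

test_that("rarefaction subsamples to exact depth without replacement", {
  t1 <- tiny_otu_table()
  r <- rarefy(t1, depth = 10, seed = 1)
  expect_true(all(colSums(r$counts) == 10))
  expect_true(all(r$counts <= t1$counts))

  # a sample already at depth is untouched; short samples drop with warning
  t2 <- tiny_otu_table()
  expect_warning(r2 <- rarefy(t2, depth = 20, seed = 1), "dropping")
  kept <- colnames(r2$counts)
  expect_true(all(colSums(t2$counts)[kept] >= 20))
  at_depth <- names(which(colSums(t2$counts) == 20))
  for (s in at_depth) expect_identical(r2$counts[, s], t2$counts[, s])

  expect_error(rarefy(t1, depth = 0), class = "hfa_value_error")
})

test_that("rarefied counts are unbiased for depth x proportion", {
  counts <- matrix(c(60L, 25L, 10L, 5L), 4, 1,
                   dimnames = list(paste0("OTU", 1:4), "s1"))
  tax <- data.frame(otu_id = paste0("OTU", 1:4), class = "Sordariomycetes")
  t1 <- otu_table(counts, tax)
  depth <- 40L
  draws <- vapply(1:400, function(s) rarefy(t1, depth, seed = s)$counts[, 1],
                  numeric(4))
  expected <- depth * counts[, 1] / sum(counts)
  # hypergeometric variance of each rarefied count
  n <- sum(counts)
  v <- depth * (counts[, 1] / n) * (1 - counts[, 1] / n) * (n - depth) / (n - 1)
  se <- sqrt(v / 400)
  expect_true(all(abs(rowMeans(draws) - expected) <= 3 * se + 1e-9))
})

test_that("relative abundance normalises each sample to one", {
  m <- matrix(c(2, 2, 4), 3, 1, dimnames = list(letters[1:3], "s1"))
  expect_equal(to_relative_abundance(m)[, 1],
               c(a = 0.25, b = 0.25, c = 0.5))
  one <- matrix(7, 1, 1, dimnames = list("a", "s1"))
  expect_equal(unname(to_relative_abundance(one)[1, 1]), 1.0)
  zero <- matrix(0, 3, 1, dimnames = list(letters[1:3], "s1"))
  expect_error(to_relative_abundance(zero), class = "hfa_empty_sample_error")
  t1 <- tiny_otu_table()
  expect_true(all(abs(colSums(to_relative_abundance(t1)) - 1) < 1e-12))
})

test_that("taxonomic aggregation conserves per-sample totals", {
  t1 <- tiny_otu_table()
  cls <- aggregate_taxa(t1, "class")
  expect_equal(colSums(cls), colSums(t1$counts))
  expect_equal(cls["Sordariomycetes", ],
               colSums(t1$counts[c("OTU1", "OTU2"), ]))
  expect_true("unclassified" %in% rownames(cls))
  phy <- aggregate_taxa(t1, "phylum")
  expect_equal(colSums(phy), colSums(t1$counts))
  expect_error(aggregate_taxa(t1, "order"))
})

test_that("guild assignment respects confidence and saprotroph precedence", {
  t1 <- tiny_otu_table()
  g <- assign_guilds(t1)
  expect_equal(unname(g["OTU1"]), "saprotroph")     # highly probable
  expect_equal(unname(g["OTU2"]), "saprotroph")     # mixed mode, precedence
  expect_equal(unname(g["OTU3"]), "symbiotroph")
  expect_equal(unname(g["OTU4"]), "unassigned")     # confidence 'possible'
  expect_equal(unname(g["OTU5"]), "pathotroph")

  g2 <- assign_guilds(t1, rule = guild_rule(saprotroph_precedence = FALSE))
  expect_equal(unname(g2["OTU2"]), "symbiotroph")

  # taxon absent from the lookup stays unassigned
  db <- t1$guilds[t1$guilds$taxon != "g1", ]
  g3 <- assign_guilds(t1, guild_db = db)
  expect_equal(unname(g3["OTU1"]), "unassigned")
})

test_that("dominant classes are the smallest prefix past the target", {
  shares <- c(a = 0.5, b = 0.3, c = 0.18, d = 0.02)
  expect_equal(dominant_classes(shares, 0.95), c("a", "b", "c"))
  expect_equal(dominant_classes(c(x = 1.0), 0.95), "x")
  ten <- stats::setNames(rep(0.1, 10), letters[1:10])
  expect_equal(length(dominant_classes(ten, 0.95)), 10L)
  # ties broken alphabetically
  expect_equal(dominant_classes(c(b = 0.5, a = 0.5), 0.4), "a")
  expect_error(dominant_classes(numeric()), class = "hfa_value_error")
})
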