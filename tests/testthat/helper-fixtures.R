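# small in-code fixtures shared across test files

# minimal 5 OTU x 4 sample table with full taxonomy and a guild lookup
tiny_otu_table <- function() {
  counts <- matrix(c(10L, 0L, 5L, 2L,
                     3L, 7L, 0L, 1L,
                     0L, 2L, 8L, 4L,
                     6L, 6L, 6L, 6L,
                     1L, 0L, 0L, 9L),
                   nrow = 5, byrow = TRUE,
                   dimnames = list(paste0("OTU", 1:5), paste0("s", 1:4)))
  tax <- data.frame(
    otu_id = paste0("OTU", 1:5),
    kingdom = "Fungi",
    phylum = c("Ascomycota", "Ascomycota", "Basidiomycota",
               "Mortierellomycota", "unclassified"),
    class = c("Sordariomycetes", "Sordariomycetes", "Tremellomycetes",
              "Mortierellomycotina", "unclassified"),
    genus = paste0("g", 1:5),
    stringsAsFactors = FALSE)
  guilds <- data.frame(
    taxon = paste0("g", 1:5),
    trophic_mode = c("Saprotroph", "Saprotroph-Symbiotroph", "Symbiotroph",
                     "Saprotroph", "Pathotroph"),
    confidence = c("highly probable", "probable", "probable",
                   "possible", "highly probable"),
    stringsAsFactors = FALSE)
  otu_table(counts, tax, guilds)
}

# a design with a single CK harvest, for focused mass/community tests
one_harvest_design <- function(month = 4L, replicates = 4L) {
  experiment_design(c("P", "C"), c("P", "C"),
                    harvests = data.frame(month = month, treatment = "CK"),
                    replicates = replicates)
}

# brute-force sliding-window truncation: recompute every window mean
oracle_truncation <- function(q, window, min_mean) {
  n <- length(q)
  if (n < window) return(if (mean(q) < min_mean) 0L else n)
  for (start in 1:(n - window + 1)) {
    if (mean(q[start:(start + window - 1)]) < min_mean) return(start - 1L)
  }
  n
}

# naive Bray-Curtis by explicit element loop
oracle_bray_curtis <- function(u, v) {
  s_min <- 0; s_sum <- 0
  for (k in seq_along(u)) {
    s_min <- s_min + min(u[k], v[k])
    s_sum <- s_sum + u[k] + v[k]
  }
  1 - 2 * s_min / s_sum
}

# one-factor pseudo-F straight from pairwise distances (for the PERMANOVA
# enumeration oracle): SST and within-group SS from squared distances
oracle_permanova_f <- function(d, groups) {
  n <- nrow(d)
  sst <- sum(d[upper.tri(d)]^2) / n
  ssw <- 0
  for (g in unique(groups)) {
    idx <- which(groups == g)
    dg <- d[idx, idx, drop = FALSE]
    ssw <- ssw + sum(dg[upper.tri(dg)]^2) / length(idx)
  }
  a <- length(unique(groups))
  ((sst - ssw) / (a - 1)) / (ssw / (n - a))
}
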