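test_that("identical pools give an all-zero enrichment matrix", {
  set.seed(1)
  m <- matrix(rpois(5 * 20, 50) + 1L, 5, 20)
  counts <- ssm_counts(strrep("A", 5), m, m)
  E <- log_enrichment(counts)
  expect_true(all(abs(E) < 1e-12))
})

test_that("a doubled frequency is one bit of enrichment", {
  cc <- equal_total_counts(sel_hot = 20, ref_hot = 10)
  counts <- ssm_counts("AA", cc$selected, cc$reference)
  E <- log_enrichment(counts, pseudocount = 0)
  expect_equal(E[1, 1], 1.0, tolerance = 1e-12)
})

test_that("an 8-fold enriched variant scores 3 bits, the rest near zero", {
  sel <- ref <- matrix(100L, 3, 20)
  sel[2, 5] <- 800L; ref[2, 5] <- 100L
  counts <- ssm_counts("AAA", sel, ref)
  E <- log_enrichment(counts, pseudocount = 0)
  # the hot cell carries 3 bits on top of the whole-pool normalization
  pool_shift <- log2(sum(ref) / sum(sel))
  expect_equal(E[2, 5], 3 + pool_shift, tolerance = 1e-12)
  rest <- E; rest[2, 5] <- NA
  expect_true(all(abs(rest - pool_shift) < 1e-12, na.rm = TRUE))
  expect_lt(max(rest, na.rm = TRUE), 0.1)
})

test_that("enrichment is antisymmetric and scale-invariant", {
  set.seed(2)
  sel <- matrix(rpois(4 * 20, 80), 4, 20)
  ref <- matrix(rpois(4 * 20, 60), 4, 20)
  counts <- ssm_counts("ACDE", sel, ref)
  E <- log_enrichment(counts, pseudocount = 1)
  swapped <- ssm_counts("ACDE", ref, sel)
  expect_equal(unclass(log_enrichment(swapped, pseudocount = 1)),
               -unclass(E), ignore_attr = TRUE, tolerance = 1e-12)
  scaled <- ssm_counts("ACDE", sel * 7L, ref)
  E2 <- log_enrichment(scaled, pseudocount = 0)
  E0 <- log_enrichment(counts, pseudocount = 0)
  expect_equal(unclass(E2), unclass(E0), ignore_attr = TRUE,
               tolerance = 1e-12)
})

test_that("masking removes exactly the parent cells", {
  set.seed(3)
  sel <- matrix(rpois(3 * 20, 50) + 1L, 3, 20)
  counts <- ssm_counts("CAD", sel, sel)
  E <- log_enrichment(counts, mask_parent = TRUE)
  expect_equal(sum(is.na(E)), 3)
  expect_true(is.na(E[1, 2]))  # C
  expect_true(is.na(E[2, 1]))  # A
  expect_true(is.na(E[3, 3]))  # D
})

test_that("entropy hits its closed-form landmarks", {
  sel <- matrix(0L, 3, 20)
  sel[1, 7] <- 500L                    # all reads one residue
  sel[2, ] <- 50L                      # uniform
  sel[3, c(2, 9)] <- c(250L, 250L)     # two equal residues
  counts <- ssm_counts("AAA", sel, sel + 1L)
  H <- position_entropy(counts)
  expect_equal(H[1], 0)
  expect_equal(H[2], log2(20), tolerance = 1e-12)
  expect_equal(H[3], 1.0, tolerance = 1e-12)
})

test_that("entropy is bounded in [0, log2 20] for arbitrary counts", {
  for (s in 1:10) {
    set.seed(s)
    sel <- matrix(rpois(6 * 20, lambda = sample(1:100, 1)), 6, 20) + 1L
    counts <- ssm_counts(strrep("G", 6), sel, sel)
    H <- position_entropy(counts)
    expect_true(all(H >= 0 & H <= log2(20) + 1e-12))
  }
})

test_that("all-zero positions are an error without pseudocount", {
  sel <- matrix(1L, 2, 20); sel[2, ] <- 0L
  counts <- ssm_counts("AA", sel, sel + 1L)
  expect_error(position_entropy(counts), "position.* 2")
  H <- position_entropy(counts, pseudocount = 1)
  expect_equal(H[2], log2(20), tolerance = 1e-12)
})

test_that("conservation classes follow the profile quantiles", {
  cls <- conservation_classes(c(0, 2, 4.3), quantiles = c(0.34, 0.67))
  expect_equal(cls, c("conserved", "intermediate", "variable"))
  expect_true(all(conservation_classes(rep(2, 8)) == "intermediate"))
})

test_that("the sorting simulator leaves its fitness footprint", {
  parent <- strrep("ACDEFGHIKLMNPQRSTVWY", 5)
  conserved <- c(3, 7, 11, 25, 40, 66, 80)
  sim <- simulate_ssm_counts(parent, conserved, depth = 10000, seed = 5)
  E <- log_enrichment(sim$counts)
  rho <- cor(as.vector(log(sim$fitness)), as.vector(E),
             method = "spearman")
  expect_gt(rho, 0.9)

  H <- position_entropy(sim$counts)
  cls <- conservation_classes(H)
  expect_gte(mean(cls[conserved] == "conserved"), 0.9)
})

test_that("count tables round-trip through both TSV dialects", {
  parent <- "ACD"
  sel <- matrix(rpois(60, 40), 3, 20, dimnames = list(NULL, aa_alphabet()))
  ref <- matrix(rpois(60, 40), 3, 20, dimnames = list(NULL, aa_alphabet()))
  counts <- ssm_counts(parent, sel, ref)

  # long form
  long <- do.call(rbind, lapply(c("selected", "reference"), function(p)
    data.frame(position = rep(1:3, 20),
               aa = rep(aa_alphabet(), each = 3),
               pool = p, count = as.vector(counts[[p]]))))
  path <- tempfile(fileext = ".tsv")
  write.table(long, path, sep = "\t", quote = FALSE, row.names = FALSE)
  back <- read_ssm_counts(parent, path = path)
  expect_equal(back$selected, counts$selected)
  expect_equal(back$reference, counts$reference)

  # matrix form
  ps <- tempfile(fileext = ".tsv"); pr <- tempfile(fileext = ".tsv")
  write.table(data.frame(position = 1:3, sel, check.names = FALSE), ps,
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(data.frame(position = 1:3, ref, check.names = FALSE), pr,
              sep = "\t", quote = FALSE, row.names = FALSE)
  back2 <- read_ssm_counts(parent, selected = ps, reference = pr)
  expect_equal(back2$selected, counts$selected)
})

test_that("count validation rejects malformed matrices", {
  expect_error(ssm_counts("AA", matrix(1, 2, 19), matrix(1, 2, 20)),
               "20 columns")
  expect_error(ssm_counts("AA", matrix(-1, 2, 20), matrix(1, 2, 20)),
               "negative")
  expect_error(ssm_counts("AAB", matrix(1, 3, 20), matrix(1, 3, 20)),
               "canonical")
  expect_error(ssm_counts("AA", matrix(1, 3, 20), matrix(1, 2, 20)),
               "rows")
})

test_that("entropy maps onto PDB B-factors per residue", {
  tb <- make_toy_bundle()
  resnos <- sort(unique(tb$atoms$resno))
  vals <- setNames(seq_along(resnos) / 10, resnos)
  path <- tempfile(fileext = ".pdb")
  write_bfactor_pdb(tb, vals, path)
  back <- bio3d::read.pdb(path, verbose = FALSE)
  b10 <- unique(back$atom$b[back$atom$resno == resnos[10]])
  expect_equal(b10, unname(vals[10]), tolerance = 1e-6)
})
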