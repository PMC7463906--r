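test_that("FASTA reading validates and round-trips", {
  aln <- marker_alignment(c(tax1 = "ACGTACGT", tax2 = "ACGTTCGT"),
                          locus = "demo")
  path <- tempfile(fileext = ".fasta")
  write_alignment_fasta(aln, path)
  back <- read_alignment_fasta(path, locus = "demo")
  expect_identical(back$taxa, aln$taxa)
  expect_identical(back$seqs, aln$seqs)

  ragged <- tempfile(fileext = ".fasta")
  writeLines(c(">a", "ACGTACGTAC", ">b", "ACGTACGTA"), ragged)
  expect_error(read_alignment_fasta(ragged), "Ragged.*'b'")

  dup <- tempfile(fileext = ".fasta")
  writeLines(c(">a", "ACGT", ">a", "ACGT"), dup)
  expect_error(read_alignment_fasta(dup), "Duplicate")

  empty <- tempfile(fileext = ".fasta")
  writeLines(character(0), empty)
  expect_error(read_alignment_fasta(empty), "Empty|read")
})

test_that("distance closed forms match hand-derived values", {
  same <- marker_alignment(c(a = "ACGTACGTAC", b = "ACGTACGTAC"))
  for (model in c("p", "JC69", "K80", "TN93")) {
    expect_equal(evolutionary_distance(same, model)[1, 2], 0, info = model)
  }

  one_diff <- marker_alignment(c(a = "ACGTACGTAC", b = "ACGTACGTAT"))
  expect_equal(evolutionary_distance(one_diff, "p")[1, 2], 0.1)
  expect_equal(evolutionary_distance(one_diff, "JC69")[1, 2],
               -0.75 * log(1 - 0.4 / 3), tolerance = 1e-12)
  expect_equal(evolutionary_distance(one_diff, "JC69")[1, 2], 0.107326,
               tolerance = 1e-5) # printed precision

  # P = 0.2 (two A<->G transitions), Q = 0.1 (one A<->C transversion)
  k80_pair <- marker_alignment(c(a = "AAAAAAAAAA", b = "GGCAAAAAAA"))
  expect_equal(evolutionary_distance(k80_pair, "K80")[1, 2],
               -0.5 * log(0.5) - 0.25 * log(0.8), tolerance = 1e-12)
  expect_equal(evolutionary_distance(k80_pair, "K80")[1, 2], 0.402360,
               tolerance = 1e-5) # printed precision
})

test_that("distances agree with ape::dist.dna on simulated data", {
  aln <- simulate_marker_alignment(default_strain_tree(), 2000, 2, seed = 21)
  bin <- ape::as.DNAbin(strsplit(tolower(aln$seqs), ""))
  for (model in c("JC69", "K80")) {
    mine <- evolutionary_distance(aln, model)
    ref <- as.matrix(ape::dist.dna(bin, model = model))
    expect_equal(mine[aln$taxa, aln$taxa], ref[aln$taxa, aln$taxa],
                 tolerance = 1e-9, ignore_attr = TRUE, info = model)
  }
  # TN93 base frequencies: per pair here, alignment-wide in ape — the
  # estimates agree closely but not to machine precision
  expect_equal(
    evolutionary_distance(aln, "TN93")[aln$taxa, aln$taxa],
    as.matrix(ape::dist.dna(bin, model = "TN93"))[aln$taxa, aln$taxa],
    tolerance = 1e-3, ignore_attr = TRUE
  )
  expect_equal(
    evolutionary_distance(aln, "p")[aln$taxa, aln$taxa],
    as.matrix(ape::dist.dna(bin, model = "raw"))[aln$taxa, aln$taxa],
    tolerance = 1e-12, ignore_attr = TRUE
  )
})

test_that("gap and N handling follows the deletion mode", {
  aln <- marker_alignment(c(a = "ACGTA-GTAC", b = "ACNTACGTAT",
                            c = "ACGTACGTAC"))
  # complete deletion drops columns 3 (N) and 6 (-): 8 comparable sites,
  # a vs b differ at the final site only
  expect_equal(evolutionary_distance(aln, "p")[1, 2], 1 / 8)
  # pairwise deletion: a vs c keeps 9 sites, all equal
  expect_equal(evolutionary_distance(aln, "p", deletion = "pairwise")[1, 3], 0)
  expect_equal(evolutionary_distance(aln, "p", deletion = "pairwise")[1, 2],
               1 / 8)
})

test_that("saturation is an error naming the pair", {
  sat <- marker_alignment(c(tax_x = "ACGTACGTACGT", tax_y = "CAGTGTACTAAC"))
  expect_error(evolutionary_distance(sat, "JC69"), "tax_x.*tax_y|Saturated")
})

test_that("JC69 correction never falls below the p-distance", {
  for (seed in 1:10) {
    aln <- simulate_marker_alignment(default_strain_tree(), 500, 2,
                                     seed = seed)
    p <- evolutionary_distance(aln, "p")
    jc <- evolutionary_distance(aln, "JC69")
    expect_true(all(jc >= p - 1e-12))
  }
})

test_that("K80 and JC69 agree on JC-generated data within sampling error", {
  aln <- simulate_marker_alignment(default_strain_tree(), 20000, 1, seed = 31)
  jc <- evolutionary_distance(aln, "JC69")
  k80 <- evolutionary_distance(aln, "K80")
  p <- evolutionary_distance(aln, "p")
  for (i in 1:3) for (j in (i + 1):4) {
    se <- sqrt(p[i, j] * (1 - p[i, j]) / 20000) / (1 - 4 * p[i, j] / 3)
    expect_lt(abs(jc[i, j] - k80[i, j]), 3 * se)
  }
})

test_that("concatenation sums lengths and validates taxa", {
  a <- simulate_marker_alignment(default_strain_tree(), 600, 1, seed = 1,
                                 locus = "ITS")
  b <- simulate_marker_alignment(default_strain_tree(), 570, 1, seed = 2,
                                 locus = "LSU")
  cc <- concatenate_alignments(list(a, b))
  expect_equal(nchar(cc$seqs[[1]]), 1170)
  expect_equal(cc$locus, "ITS_LSU")
  expect_identical(concatenate_alignments(list(a))$seqs, a$seqs)
  d <- marker_alignment(c(other1 = "ACGT", other2 = "ACGA"))
  expect_error(concatenate_alignments(list(a, d)), "differ")
})

test_that("neighbor joining recovers the worked additive example", {
  D <- sym_from_lower(c(3, 5, 6, 6, 7, 7), LETTERS[1:4])
  tr <- neighbor_joining(D)
  # path metric reproduces D exactly
  expect_equal(cophenetic(tr)[LETTERS[1:4], LETTERS[1:4]], D,
               tolerance = 1e-9, ignore_attr = TRUE)
  # split AB|CD with leaf edges 1,2,3,4 and internal edge 1
  leaf_edges <- setNames(
    tr$edge.length[match(1:4, tr$edge[, 2])], tr$tip.label
  )
  expect_equal(unname(leaf_edges[LETTERS[1:4]]), c(1, 2, 3, 4))
  internal <- tr$edge.length[tr$edge[, 2] > 4]
  expect_equal(internal, 1)
})

test_that("three-taxon trees follow the closed-form star formulas", {
  D <- sym_from_lower(c(3, 4, 5), c("a", "b", "c"))
  tr <- neighbor_joining(D)
  edges <- setNames(tr$edge.length[match(1:3, tr$edge[, 2])], tr$tip.label)
  expect_equal(unname(edges[c("a", "b", "c")]), c(1, 2, 3))
  expect_error(neighbor_joining(D[1:2, 1:2]), ">= 3")
})

test_that("neighbor joining is exact on random additive matrices", {
  set.seed(99)
  for (rep in 1:30) {
    n <- sample(4:8, 1)
    phy <- ape::rtree(n, br = function(k) runif(k, 0.1, 2))
    D <- cophenetic(phy)
    labs <- sort(rownames(D))
    tr <- neighbor_joining(D[labs, labs])
    expect_lt(max(abs(cophenetic(tr)[labs, labs] - D[labs, labs])), 1e-9)
  }
})

test_that("bootstrap supports behave at the boundaries", {
  # one repeated column pattern: every replicate rebuilds the same tree
  block <- c(a = "A", b = "A", c = "G", d = "G")
  aln <- marker_alignment(setNames(strrep(block, 40), names(block)))
  tr <- bootstrap_support(aln, model = "p", n_reps = 30, seed = 1)
  expect_true(all(tr$node.label == 100))

  aln2 <- simulate_marker_alignment(default_strain_tree(), 300, 1, seed = 5)
  tr2 <- bootstrap_support(aln2, n_reps = 1, seed = 2)
  expect_true(all(tr2$node.label %in% c(0L, 100L)))
})

test_that("bootstrap is reproducible and supports the true split", {
  aln <- simulate_marker_alignment(
    "((A:0.05,B:0.05):0.03,(C:0.05,D:0.05):0.03);", 5000, 1, seed = 17
  )
  tr <- bootstrap_support(aln, n_reps = 100, seed = 3)
  tr_again <- bootstrap_support(aln, n_reps = 100, seed = 3)
  expect_identical(tr$node.label, tr_again$node.label)
  # the AB|CD split is the only internal edge; its support must be high
  expect_gte(max(tr$node.label), 95)
})

test_that("newick export keeps supports and quotes awkward labels", {
  aln <- simulate_marker_alignment(default_strain_tree(), 400, 1, seed = 6)
  tr <- bootstrap_support(aln, n_reps = 20, seed = 1)
  path <- tempfile(fileext = ".nwk")
  write_newick(tr, path)
  back <- ape::read.tree(path)
  expect_setequal(back$tip.label, tr$tip.label)
  expect_true(all(stats::na.omit(as.integer(back$node.label)) %in% 0:100))

  star <- ape::read.tree(text = "(one:1,two:2,three:3);")
  star$tip.label[1] <- "strain one"
  p2 <- tempfile(fileext = ".nwk")
  write_newick(star, p2)
  expect_true(any(grepl("'strain one'", readLines(p2), fixed = TRUE)))
  expect_setequal(read_newick(p2)$tip.label,
                  c("strain one", "two", "three"))

  # plain 3-leaf star round-trips
  p3 <- tempfile(fileext = ".nwk")
  write_newick(ape::read.tree(text = "(one:1,two:2,three:3);"), p3)
  rt <- read_newick(p3)
  expect_setequal(rt$tip.label, c("one", "two", "three"))
  expect_equal(sort(rt$edge.length), c(1, 2, 3))
})
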