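# SMILES parsing, atom featurization, padding/batching, protein tokenization,
# interaction tables and dataset splitting.

test_that("smiles_to_graph builds heavy-atom graphs with perceived chemistry", {
  g1 <- smiles_to_graph("C")
  expect_equal(g1$n_real, 1L)
  expect_equal(nrow(g1$edges), 0L)
  g2 <- smiles_to_graph("CC")
  expect_equal(g2$n_real, 2L)
  expect_equal(nrow(g2$edges), 1L)
  # implicit hydrogens are features, not nodes
  expect_equal(g2$atoms$total_h, c(3L, 3L))
  expect_error(smiles_to_graph("C1CC"), "cannot parse SMILES 'C1CC'")
  expect_error(smiles_to_graph(""), "empty")
})

test_that("featurization follows the frozen 74-dim 8-block layout", {
  blocks <- atom_feature_blocks()
  expect_equal(nrow(blocks), 8L)
  expect_equal(sum(blocks$width), 74L)
  expect_equal(atom_feature_dim(), 74L)

  g <- smiles_to_graph("CCO")
  X <- featurize_atoms(g)
  expect_identical(dim(X), c(3L, 74L))
  # every one-hot block of every real atom has exactly one 1
  onehot <- blocks[!(blocks$block %in% c("formal_charge", "radical_electrons",
                                         "aromatic")), ]
  for (r in seq_len(nrow(X))) {
    for (b in seq_len(nrow(onehot))) {
      expect_equal(sum(X[r, onehot$start[b]:onehot$end[b]]), 1)
    }
  }
  # neutral carbon: formal charge slot 0
  fc <- blocks[blocks$block == "formal_charge", ]
  expect_equal(X[1, fc$start], 0)
})

test_that("aromaticity and charge are perceived before featurization", {
  blocks <- atom_feature_blocks()
  arom <- blocks[blocks$block == "aromatic", "start"]
  Xbenz <- featurize_atoms(smiles_to_graph("c1ccccc1"))
  expect_true(all(Xbenz[, arom] == 1))
  Xeth <- featurize_atoms(smiles_to_graph("CC"))
  expect_true(all(Xeth[, arom] == 0))
  fc <- blocks[blocks$block == "formal_charge", "start"]
  Xchg <- featurize_atoms(smiles_to_graph("[NH4+]"))
  expect_equal(Xchg[1, fc], 1)
})

test_that("featurization is deterministic", {
  expect_identical(featurize_atoms(smiles_to_graph("OC(=O)c1ccccc1")),
                   featurize_atoms(smiles_to_graph("OC(=O)c1ccccc1")))
})

test_that("pad_batch pads with all-zero dummies and correct masks", {
  g <- smiles_to_graph("CCCCC")  # 5 atoms
  pb <- pad_batch(list(g), max_nodes = 50L)
  expect_equal(sum(pb$node_mask), 5L)
  expect_equal(length(pb$node_mask), 50L)
  expect_true(all(pb$features[!pb$node_mask, ] == 0))
  # no edges touch dummy nodes
  expect_true(all(Matrix::rowSums(pb$adjacency)[!pb$node_mask] == 0))
  expect_error(pad_batch(list(smiles_to_graph("CCCCC")), max_nodes = 4L),
               "5 atoms > max_nodes = 4")
})

test_that("pad_batch stacks multiple graphs block-diagonally", {
  gs <- lapply(c("CC", "CCO", "C"), smiles_to_graph)
  pb <- pad_batch(gs)
  expect_equal(pb$max_nodes, 3L)
  expect_equal(pb$n_real, c(2L, 3L, 1L))
  # adjacency has no entries between different graphs
  A <- as.matrix(pb$adjacency)
  expect_true(all(A[1:3, 4:9] == 0))
  expect_true(all(A[4:6, 7:9] == 0))
})

test_that("protein tokenizer covers the 25-symbol alphabet deterministically", {
  expect_equal(nchar(PROTEIN_ALPHABET), 25L)
  t1 <- tokenize_protein("ACD")
  expect_equal(t1$length, 3L)
  expect_true(all(t1$indices >= 1 & t1$indices <= 25))
  expect_identical(tokenize_protein("MKVLA")$indices,
                   tokenize_protein("MKVLA")$indices)
  # out-of-alphabet characters map to the catch-all X (last index)
  expect_equal(tokenize_protein("J*7")$indices, rep(25L, 3))
  expect_equal(tokenize_protein("acd")$indices, tokenize_protein("ACD")$indices)
  expect_error(tokenize_protein(""), "empty")
})

test_that("interaction tables round-trip through CSV with validation", {
  df <- data.frame(smiles = c("CC", "CCO", "C"),
                   sequence = c("MKV", "ACDE", "HWKWY"),
                   label = c(1L, 0L, 1L))
  path <- tempfile(fileext = ".csv")
  write_interactions(df, path)
  back <- read_interactions(path)
  expect_equal(back, df)

  writeLines("smiles,sequence,label", path)
  expect_equal(nrow(read_interactions(path)), 0L)

  writeLines(c("smiles,sequence,label", "CC,MKV,0.5"), path)
  expect_error(read_interactions(path), "non-binary label '0.5' at data row 1")

  writeLines(c("smiles,label", "CC,1"), path)
  expect_error(read_interactions(path), "missing column")
})

test_that("split_dataset partitions 7:1:2 deterministically", {
  recs <- data.frame(smiles = paste0("C", 1:100), sequence = "MKV", label = 0L)
  sp <- split_dataset(recs, seed = 7L)
  expect_equal(nrow(sp$train), 70L)
  expect_equal(nrow(sp$val), 10L)
  expect_equal(nrow(sp$test), 20L)
  all_ids <- sort(c(sp$train$smiles, sp$val$smiles, sp$test$smiles))
  expect_equal(all_ids, sort(recs$smiles))  # partition: union = input
  sp2 <- split_dataset(recs, seed = 7L)
  expect_identical(sp$test$smiles, sp2$test$smiles)
  expect_false(identical(split_dataset(recs, seed = 8L)$test$smiles,
                         sp$test$smiles))
})

test_that("split sizes always sum to n (property over many n)", {
  for (n in c(10:25, 99, 100, 101, 500, 1000)) {
    recs <- data.frame(smiles = as.character(seq_len(n)), sequence = "M",
                       label = 0L)
    sp <- split_dataset(recs, seed = 1L)
    expect_equal(nrow(sp$train) + nrow(sp$val) + nrow(sp$test), n)
    expect_equal(nrow(sp$train), floor(0.7 * n))
  }
  expect_error(split_dataset(data.frame(smiles = "C", sequence = "M",
                                        label = 0L), seed = 1),
               "n >= 10")
})

test_that("read_fasta parses simple records", {
  path <- tempfile(fileext = ".fa")
  writeLines(c(">p1", "MKVL", "AAC", ">p2", "HWKWY"), path)
  fa <- read_fasta(path)
  expect_equal(unname(fa), c("MKVLAAC", "HWKWY"))
  expect_equal(names(fa), c("p1", "p2"))
})
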