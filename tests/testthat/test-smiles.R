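test_that("parse_smiles builds correct heavy-atom graphs", {
  g <- parse_smiles("C1CCCCC1")
  expect_equal(nrow(g$atoms), 6)
  expect_equal(nrow(g$bonds), 6)
  expect_true(all(g$atoms$element == "C"))
  expect_true(all(g$bonds$order == 1))

  g <- parse_smiles("COC")
  expect_equal(g$atoms$element, c("C", "O", "C"))
  expect_equal(nrow(g$bonds), 2)
  expect_true(all(g$bonds$order == 1))

  g <- parse_smiles("CC(=O)O")
  expect_equal(sort(g$atoms$element), c("C", "C", "O", "O"))
  expect_equal(sort(g$bonds$order), c(1, 1, 2))

  # branches and ring closures together
  g <- parse_smiles("CC1CC(C)C1")
  expect_equal(nrow(g$atoms), 6)
  expect_equal(nrow(g$bonds), 6)

  # dot notation: disconnected components in one graph
  g <- parse_smiles("O.O")
  expect_equal(nrow(g$atoms), 2)
  expect_equal(nrow(g$bonds), 0)
})

test_that("bracket atoms carry charge, hydrogen count and isotope syntax", {
  g <- parse_smiles("[NH4+]")
  expect_equal(g$atoms$element, "N")
  expect_equal(g$atoms$charge, 1L)
  expect_equal(g$atoms$hcount, 4L)

  g <- parse_smiles("C[N+](=O)[O-]")
  expect_equal(g$atoms$charge, c(0L, 1L, 0L, -1L))

  g <- parse_smiles("[13C]")
  expect_equal(g$atoms$element, "C")

  g <- parse_smiles("C[C@H](N)O")
  expect_equal(g$atoms$chiral[2], "@")
  expect_equal(g$atoms$hcount[2], 1L)
})

test_that("invalid SMILES are rejected with the input named", {
  err <- tryCatch(parse_smiles("C1CC"), error = identity)
  expect_s3_class(err, "molforge_invalid_smiles")
  expect_match(conditionMessage(err), "C1CC", fixed = TRUE)

  expect_error(parse_smiles("C("), class = "molforge_invalid_smiles")
  expect_error(parse_smiles("C)"), class = "molforge_invalid_smiles")
  expect_error(parse_smiles("CC=(C)"), class = "molforge_invalid_smiles")
  expect_error(parse_smiles("Zz"), class = "molforge_invalid_smiles")
  expect_error(parse_smiles("C=.C"), class = "molforge_invalid_smiles")
  expect_error(parse_smiles("   "), class = "molforge_empty_input")
})

test_that("kekulization yields alternating discrete bond orders", {
  b <- parse_smiles("c1ccccc1")
  expect_equal(sort(b$bonds$order), c(1, 1, 1, 2, 2, 2))
  # every aromatic carbon ends up with exactly one double bond
  for (at in 1:6) {
    orders <- b$bonds$order[b$bonds$a == at | b$bonds$b == at]
    expect_equal(sort(orders), c(1, 2))
  }

  # heteroaromatics: pyrrole nitrogen keeps its H and takes no double bond
  p <- parse_smiles("c1cc[nH]c1")
  n_idx <- which(p$atoms$element == "N")
  expect_equal(sum(p$bonds$order[p$bonds$a == n_idx | p$bonds$b == n_idx] == 2), 0)
  expect_equal(sum(p$bonds$order == 2), 2)

  # pyridine nitrogen participates in the alternation
  py <- parse_smiles("c1ccncc1")
  expect_equal(sum(py$bonds$order == 2), 3)

  # an odd all-carbon aromatic ring admits no perfect matching
  expect_error(parse_smiles("c1cccc1"), class = "molforge_invalid_smiles")
})

test_that("parsed graphs agree with an independent cheminformatics toolkit", {
  library(ChemmineR)
  for (smi in c("c1ccccc1", "c1ccc2ccccc2c1", "Cn1cnc2c1c(=O)n(C)c(=O)n2C",
                "CC(=O)Oc1ccccc1C(=O)O", "c1ccoc1", "c1cc[nH]c1",
                "C[N+](=O)[O-]", "OCC1OC(O)C(O)C(O)C1O")) {
    ours <- parse_smiles(smi)
    sdf <- suppressWarnings(smiles2sdf(smi))[[1]]
    expect_equal(nrow(ours$atoms), nrow(atomblock(sdf)), info = smi)
    bb <- bondblock(sdf)
    expect_equal(nrow(ours$bonds), nrow(bb), info = smi)
    expect_equal(sort(ours$bonds$order), sort(as.integer(bb[, 3])), info = smi)
  }
})

test_that("resolve_input maps trivial names offline and passes SMILES through", {
  expect_equal(resolve_input("ethanol"), "CCO")
  expect_equal(resolve_input("Methanol"), "CO")
  expect_equal(resolve_input("  cyclohexane "), "C1CCCCC1")
  expect_equal(resolve_input("CCO"), "CCO")
  expect_equal(resolve_input("notaname"), "notaname")
  expect_error(resolve_input("   "), class = "molforge_empty_input")
})

test_that("comma-separated batches split in order with trimming", {
  b <- split_batch_text("CCO, CO")
  expect_equal(as.character(b), c("CCO", "CO"))
  expect_equal(attr(b, "source"), "inline")
  expect_equal(as.character(split_batch_text("C")), "C")
  expect_error(split_batch_text("CCO,,CO"), class = "molforge_empty_token")
  expect_error(split_batch_text(""), class = "molforge_empty_input")
})

test_that("CSV batches read the first column of non-empty rows in order", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("CCO", "CO", "", "COC"), f)
  b <- read_batch_csv(f)
  expect_equal(as.character(b), c("CCO", "CO", "COC"))
  expect_equal(attr(b, "source"), "csv")

  # extra columns are ignored; header can be skipped
  writeLines(c("smiles,label", "CCO,ethanol"), f)
  expect_equal(as.character(read_batch_csv(f, header = TRUE)), "CCO")

  writeLines(character(0), f)
  expect_error(read_batch_csv(f), class = "molforge_empty_file")
  expect_error(read_batch_csv(file.path(tempdir(), "nope.csv")),
               class = "molforge_file_not_found")
})
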