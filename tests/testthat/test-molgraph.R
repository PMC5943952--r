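# Molecular graph model, SMILES/SDF input and the normalization rules.

test_that("SMILES reading produces the expected graphs and hydrogen counts", {
  eth <- read_smiles("CCO")
  expect_equal(nrow(eth$atoms), 3)
  expect_equal(eth$atoms$element, c("C", "C", "O"))
  expect_equal(eth$atoms$hcount, c(3L, 2L, 1L))
  expect_equal(nrow(eth$bonds), 2)
  expect_true(all(eth$bonds$order == 1L))

  pyr <- read_smiles("c1ccncc1")
  expect_equal(nrow(pyr$atoms), 6)
  expect_equal(sum(pyr$bonds$order == 4L), 6)

  bf4 <- read_smiles("F[B-](F)(F)F")
  b <- which(bf4$atoms$element == "B")
  expect_equal(bf4$atoms$charge[b], -1L)
  expect_equal(sum(bf4$atoms$element == "F"), 4)
  expect_equal(bf4$atoms$hcount[b], 0L)

  expect_error(read_smiles("C1CC"), "parse failure")   # unmatched ring bond
})

test_that("element whitelist gating flags offending elements", {
  expect_true(validate_elements(read_smiles("CCO"))$eligible)
  fe <- molgraph(data.frame(element = "Fe", charge = 0L, hcount = 0L))
  v <- validate_elements(fe)
  expect_false(v$eligible)
  expect_equal(v$offending, "Fe")
  expect_true(validate_elements(read_smiles("F[B-](F)(F)F"))$eligible)
})

test_that("SDF files round-trip atoms, charges and bond orders exactly", {
  fx <- fixture_molecules()
  ids <- c("ethanol", "benzene", "1-methylimidazolium", "methylsulfonate",
           "tetrafluoroborate", "acetic_acid")
  path <- tempfile(fileext = ".sdf")
  write_sdf(lapply(fx[ids], `[[`, "mol"), path)
  back <- read_sdf(path)
  expect_length(back, length(ids))
  for (k in seq_along(ids)) {
    orig <- fx[[ids[k]]]$mol
    expect_equal(back[[k]]$atoms$element, orig$atoms$element, info = ids[k])
    expect_equal(back[[k]]$atoms$charge, orig$atoms$charge, info = ids[k])
    expect_equal(back[[k]]$atoms$hcount, orig$atoms$hcount, info = ids[k])
    expect_equal(back[[k]]$bonds, orig$bonds, info = ids[k])
  }
})

test_that("corrupt SDF records are reported per record, others survive", {
  fx <- fixture_molecules()
  path <- tempfile(fileext = ".sdf")
  write_sdf(list(fx$ethanol$mol, fx$benzene$mol, fx$methanol$mol), path)
  lines <- readLines(path)
  counts_lines <- grep("V2000", lines)
  lines[counts_lines[2]] <- "garbage counts line"
  writeLines(lines, path)
  expect_warning(back <- read_sdf(path), "record 2")
  expect_length(back, 2)
  errs <- attr(back, "errors")
  expect_equal(errs$record, 2L)

  # unsupported element: record kept, flagged, not dropped
  se <- molgraph(data.frame(element = c("Se", "C"), charge = 0L,
                            hcount = c(1L, 3L)),
                 data.frame(i = 1, j = 2, order = 1), name = "selenol")
  path2 <- tempfile(fileext = ".sdf")
  write_sdf(list(se, fx$ethanol$mol), path2)
  back2 <- read_sdf(path2)
  expect_length(back2, 2)
  expect_equal(back2[[1]]$offending_elements, "Se")
  expect_equal(back2[[2]]$offending_elements, character(0))
})

test_that("SDF data fields are retained and can drive the compound id", {
  fx <- fixture_molecules()
  mol <- fx$ethanol$mol
  mol$props <- c(CAS = "64-17-5")
  path <- tempfile(fileext = ".sdf")
  write_sdf(mol, path)
  back <- read_sdf(path, id_field = "CAS")
  expect_equal(back[[1]]$props[["CAS"]], "64-17-5")
  expect_equal(back[[1]]$id, "64-17-5")
})

test_that("amidinium normalization moves the charge to the central carbon", {
  # 2-methylimidazolium: charge drawn on N ends up on C2, C2-N bonds aromatic
  m <- read_smiles("Cc1[nH]cc[nH+]1")
  cpos <- which(m$atoms$element == "C" & m$atoms$charge == 1L)
  expect_length(cpos, 1)
  nn <- m$bonds[m$bonds$i == cpos | m$bonds$j == cpos, ]
  n_arom <- nn[nn$order == 4L, ]
  expect_equal(nrow(n_arom), 2)
  expect_equal(sum(m$atoms$charge), 1L)

  # guanidinium: charge on central C, three aromatic C-N bonds
  g <- read_smiles("NC(N)=[NH2+]")
  cg <- which(g$atoms$element == "C")
  expect_equal(g$atoms$charge[cg], 1L)
  cb <- g$bonds[g$bonds$i == cg | g$bonds$j == cg, ]
  expect_equal(sort(cb$order), c(4L, 4L, 4L))
  expect_true(all(g$atoms$charge[g$atoms$element == "N"] == 0L))
  expect_equal(g$atoms$hcount[g$atoms$element == "N"], c(2L, 2L, 2L))

  # neutral imidazole is untouched by the rewrite
  raw <- read_smiles("c1c[nH]cn1", normalize = FALSE)
  norm <- read_smiles("c1c[nH]cn1", normalize = TRUE)
  expect_equal(norm$atoms, raw$atoms)
  expect_equal(norm$bonds, raw$bonds)
})

test_that("normalization is idempotent and conserves formula and net charge", {
  for (smi in c("Cc1[nH]cc[nH+]1", "Cn1cc[nH+]c1", "NC(N)=[NH2+]",
                "c1cc[nH+]cc1", "C[n+]1ccccc1", "CCO")) {
    m1 <- read_smiles(smi)
    m2 <- normalize_amidinium(m1)
    expect_equal(m2$atoms, m1$atoms, info = smi)
    expect_equal(m2$bonds, m1$bonds, info = smi)
    raw <- read_smiles(smi, normalize = FALSE)
    expect_equal(sum(m1$atoms$charge), sum(raw$atoms$charge), info = smi)
    expect_equal(table(m1$atoms$element), table(raw$atoms$element), info = smi)
    expect_equal(sum(m1$atoms$hcount), sum(raw$atoms$hcount), info = smi)
  }
})

test_that("five-membered heteroaromatics are kept in Kekule form", {
  for (smi in c("c1ccsc1", "c1ccoc1", "c1cc[nH]c1")) {
    m <- read_smiles(smi)
    expect_equal(sum(m$bonds$order == 4L), 0, info = smi)
    expect_equal(sum(m$bonds$order == 2L), 2, info = smi)
  }
  # while six-membered rings are aromatic even from a Kekule drawing
  k <- read_smiles("C1=CC=CC=C1")
  expect_equal(sum(k$bonds$order == 4L), 6)
})

test_that("graph construction validates bonds", {
  at <- data.frame(element = c("C", "C"), charge = 0L, hcount = 3L)
  expect_error(molgraph(at, data.frame(i = 1, j = 3, order = 1)), "out of range")
  expect_error(molgraph(at, data.frame(i = 1, j = 1, order = 1)), "self-bond")
  expect_error(molgraph(at, data.frame(i = c(1, 2), j = c(2, 1), order = 1)),
               "duplicate")
  expect_error(molgraph(data.frame(element = "Xx", charge = 0L, hcount = 0L)),
               "unknown element")
})
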