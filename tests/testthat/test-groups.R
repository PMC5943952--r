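# Group perception: atom types, canonical neighbour strings, special groups.

test_that("fixture molecules reproduce their frozen decompositions exactly", {
  fx <- fixture_molecules()
  expect_gte(length(fx), 15)
  for (f in fx) {
    gc <- perceive(f$mol, h_acceptor = TRUE)
    expect_identical(sorted_counts(gc$counts), sorted_counts(f$expected),
                     info = f$id)
    expect_equal(unname(gc$special[names(f$special)]), unname(f$special),
                 info = f$id)
  }
})

test_that("atom typing follows element, charge, bond pattern and aromaticity", {
  fx <- fixture_molecules()
  bf4 <- fx$tetrafluoroborate$mol
  expect_equal(atom_type(bf4, which(bf4$atoms$element == "B")), "B(-)")
  ms <- fx$methylsulfonate$mol
  expect_equal(atom_type(ms, which(ms$atoms$element == "S")), "S4")
  im <- fx$`2-methylimidazolium`$mol
  c2 <- which(im$atoms$element == "C" & im$atoms$charge == 1L)
  expect_equal(atom_type(im, c2), "C(+) aromatic")

  thiol <- read_smiles("CCS")
  expect_equal(atom_type(thiol, which(thiol$atoms$element == "S")), "S2")
  nitrile <- read_smiles("CC#N")
  sp_c <- which(nitrile$atoms$hcount == 0 & nitrile$atoms$element == "C")
  expect_equal(atom_type(nitrile, sp_c), "C sp")

  # hydrogens and halogens are never group centers
  ch3br <- read_smiles("CBr")
  expect_error(atom_type(ch3br, which(ch3br$atoms$element == "Br")),
               "not a group center")
})

test_that("neighbour strings follow the canonical grammar", {
  # carboxyl carbon and hydroxyl oxygen of acetic acid
  aa <- read_smiles("CC(=O)O")
  cx <- which(aa$atoms$element == "C" & aa$atoms$hcount == 0L)
  expect_equal(canonical_neighbor_string(aa, cx), "CO=O")

  # ester oxygen of methyl acetate: two carbons, one of them a pi system
  ma <- read_smiles("COC(C)=O")
  inc <- groupadd:::incident_bonds(ma)
  est_o <- which(vapply(seq_len(nrow(ma$atoms)), function(a)
    ma$atoms$element[a] == "O" && length(inc[[a]]) == 2, TRUE))
  expect_equal(canonical_neighbor_string(ma, est_o), "C2(pi)")

  # phenol oxygen
  ph <- read_smiles("Oc1ccccc1")
  expect_equal(canonical_neighbor_string(ph, which(ph$atoms$element == "O")),
               "HC(pi)")

  # nitro group: charge markers collect at the end of the string
  nb <- read_smiles("O=[N+]([O-])c1ccccc1")
  np <- which(nb$atoms$element == "N")
  expect_equal(atom_type(nb, np), "N(+) sp2")
  expect_equal(canonical_neighbor_string(nb, np), "CO=O(-)")
  ipso <- which(vapply(seq_len(nrow(nb$atoms)), function(a)
    nb$atoms$element[a] == "C" && nb$atoms$hcount[a] == 0, TRUE))
  expect_equal(canonical_neighbor_string(nb, ipso), ":C2N(+)")

  # carboxylate
  acet <- read_smiles("CC(=O)[O-]")
  cx2 <- which(acet$atoms$element == "C" & acet$atoms$hcount == 0L)
  expect_equal(canonical_neighbor_string(acet, cx2), "CO=O(-)")
  expect_equal(atom_type(acet, cx2), "C sp2")

  # iodine is written J, halogens sort after the main-group elements
  mei <- read_smiles("ICCl")
  c1 <- which(mei$atoms$element == "C")
  expect_equal(canonical_neighbor_string(mei, c1), "H2ClJ")

  # aromatic amine nitrogen: pi count replaces per-neighbour markers
  an <- read_smiles("Nc1ccccc1")
  expect_equal(canonical_neighbor_string(an, which(an$atoms$element == "N")),
               "H2C(pi)")
  dpa <- read_smiles("O(c1ccccc1)c1ccccc1")
  expect_equal(canonical_neighbor_string(dpa, which(dpa$atoms$element == "O")),
               "C2(2pi)")
})

test_that("group centers exclude terminal multiply-bonded O/N/S and O(-)", {
  # acetic acid: 4 heavy atoms but 3 centers (carbonyl O is a neighbour only)
  aa <- read_smiles("CC(=O)O")
  expect_equal(perceive(aa)$n_centers, 3)
  # acetonitrile: nitrile N is not a center
  expect_equal(perceive(read_smiles("CC#N"))$n_centers, 2)
  # methylsulfonate: only C and S are centers
  expect_equal(perceive(read_smiles("CS(=O)(=O)[O-]"))$n_centers, 2)
  # but divalent anionic N is a center (bis-sulfonyl amide)
  fx <- fixture_molecules(parse = FALSE)
  expect_true("N(-)|S2" %in% names(fx$bistriflamide$expected))
  # center conservation for molecules without excluded terminals
  hex <- read_smiles("CCCCCC")
  expect_equal(perceive(hex)$n_centers, 6)
  bz <- read_smiles("c1ccccc1")
  expect_equal(sum(perceive(bz)$counts), 6)
})

test_that("perception is invariant under atom reordering", {
  fx <- fixture_molecules()
  for (id in c("toluene", "salicylaldehyde", "1-methylimidazolium",
               "bistriflamide")) {
    ref <- perceive(fx[[id]]$mol, h_acceptor = TRUE)
    for (s in 1:3) {
      per <- perceive(permute_mol(fx[[id]]$mol, seed = s), h_acceptor = TRUE)
      expect_identical(sorted_counts(per$counts), sorted_counts(ref$counts),
                       info = paste(id, s))
      expect_identical(per$special, ref$special, info = paste(id, s))
    }
  }
})

test_that("hydrocarbon special groups count carbons of pure hydrocarbons only", {
  expect_equal(detect_hydrocarbon_special(read_smiles("CCCCCC")),
               c(alkane_C = 6L, unsatHC_C = 0L))
  expect_equal(detect_hydrocarbon_special(read_smiles("Cc1ccccc1")),
               c(alkane_C = 0L, unsatHC_C = 7L))
  expect_equal(detect_hydrocarbon_special(read_smiles("C=CC")),
               c(alkane_C = 0L, unsatHC_C = 3L))
  expect_equal(detect_hydrocarbon_special(read_smiles("CCO")),
               c(alkane_C = 0L, unsatHC_C = 0L))
})

test_that("hydrogen-bond detector finds 5- to 7-membered donor/acceptor rings", {
  expect_equal(detect_h_acceptor(read_smiles("O=Cc1ccccc1O")), 1L)  # salicylaldehyde
  expect_equal(detect_h_acceptor(read_smiles("Oc1ccccc1")), 0L)     # phenol
  expect_equal(detect_h_acceptor(read_smiles("OCCO")), 1L)          # ethylene glycol
  # detector is off by default in perception
  expect_equal(perceive(read_smiles("OCCO"))$special[["h_acceptor"]], 0L)
  expect_equal(perceive(read_smiles("OCCO"), h_acceptor = TRUE)$special[["h_acceptor"]], 1L)
})

test_that("strict perception rejects labels outside the table vocabulary", {
  pme3 <- read_smiles("CP(C)C")   # trivalent phosphine: no table row exists
  expect_error(perceive(pme3, strict = TRUE), "outside the table vocabulary")
  lenient <- perceive(pme3)
  expect_true(any(grepl("^P3", names(lenient$counts))))
  # whitelist violations always error
  fe <- molgraph(data.frame(element = "Fe", charge = 0L, hcount = 0L))
  expect_error(perceive(fe), "element not supported: Fe")
})
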