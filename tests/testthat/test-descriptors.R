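# Geometric, charge and dipole descriptors, and matrix assembly.

test_that("descriptor_spec enforces arity and argument rules", {
  expect_error(descriptor_spec("distance", 1), "2 atom")
  expect_error(descriptor_spec("dihedral", c(1, 2, 3)), "4 atom")
  expect_error(descriptor_spec("distance", c(2, 2)), "repeated")
  expect_error(descriptor_spec("frequency"), "mode")
  expect_error(descriptor_spec("dipole_component"), "axis")
  sp <- descriptor_spec("charge_difference", c(3, 5))
  expect_equal(sp$label, "charge_difference(3,5)")
})

test_that("distances and dihedrals match hand values and the oracle", {
  s <- structure_3d("t", c("C", "C"), rbind(c(0, 0, 0), c(3, 4, 0)))
  expect_equal(atom_distance(s, 1, 2), 5)
  # planar trans chain -> 180 degrees, inside (-180, 180]
  chain <- structure_3d("tr", rep("C", 4),
                        rbind(c(0, 0, 0), c(1.5, 0, 0), c(2.25, 1.3, 0),
                              c(3.75, 1.3, 0)))
  expect_equal(dihedral_angle(chain, 1, 2, 3, 4), 180)
  set.seed(41)
  for (rep in 1:25) {
    p <- matrix(rnorm(12, sd = 2), 4)
    s4 <- structure_3d("r", rep("C", 4), p)
    expect_equal(dihedral_angle(s4, 1, 2, 3, 4),
                 dihedral_oracle(p[1, ], p[2, ], p[3, ], p[4, ]),
                 tolerance = 1e-9)
  }
})

test_that("geometric and Sterimol descriptors are rigid-motion invariant", {
  set.seed(42)
  lib <- gen_toy_structures(c("NO2", "OMe"))
  specs <- list(descriptor_spec("distance", c(3, 9)),
                descriptor_spec("bond_length", c(7, 8)),
                descriptor_spec("dihedral", c(2, 1, 7, 8)),
                descriptor_spec("sterimol_B5", c(1, 7)))
  for (s in lib$structures) for (rep in 1:5) {
    mo <- random_rigid_motion()
    s2 <- apply_rigid(s, mo)
    for (sp in specs)
      expect_equal(compute_descriptor(s2, sp), compute_descriptor(s, sp),
                   tolerance = 1e-6)
  }
})

test_that("charge descriptors: lookup, zero difference, antisymmetry", {
  ch <- data.frame(structure = "s1", atom_index = 1:4,
                   charge = c(-0.3, 0.45, 0.45, -0.1))
  ann <- read_annotations(ch)
  s <- structure_3d("s1", rep("C", 4), matrix(rnorm(12), 4))
  expect_equal(compute_descriptor(s, descriptor_spec("charge", 1), ann), -0.3)
  expect_equal(compute_descriptor(s, descriptor_spec("charge_difference",
                                                     c(2, 3)), ann), 0)
  set.seed(43)
  for (rep in 1:10) {
    ij <- sample(4, 2)
    d1 <- compute_descriptor(s, descriptor_spec("charge_difference", ij), ann)
    d2 <- compute_descriptor(s, descriptor_spec("charge_difference", rev(ij)),
                             ann)
    expect_equal(d1, -d2)
  }
  expect_error(compute_descriptor(s, descriptor_spec("charge", 9), ann),
               "no charge")
})

test_that("two-point dipole and alternating-square cancellation", {
  s <- structure_3d("hh", c("H", "H"), rbind(c(0, 0, 0), c(1, 0, 0)))
  d <- dipole_from_charges(s, c(0.5, -0.5), origin = c(7, -2, 3))
  expect_equal(d$mu_vec, c(-0.5, 0, 0), tolerance = 1e-12)
  expect_equal(d$mu_tot, 0.5, tolerance = 1e-12)
  sq <- structure_3d("sq", rep("H", 4),
                     rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0)))
  expect_equal(dipole_from_charges(sq, c(0.3, -0.3, 0.3, -0.3))$mu_tot, 0,
               tolerance = 1e-12)
})

test_that("dipole is origin-independent iff the total charge vanishes", {
  set.seed(44)
  s <- structure_3d("r", rep("C", 6), matrix(rnorm(18), 6))
  q_neutral <- rnorm(6)
  q_neutral <- q_neutral - mean(q_neutral)
  q_charged <- q_neutral + 0.2
  ref_n <- dipole_from_charges(s, q_neutral)$mu_vec
  ref_c <- dipole_from_charges(s, q_charged)$mu_vec
  shifted <- FALSE
  for (rep in 1:10) {
    o <- rnorm(3, sd = 4)
    expect_equal(dipole_from_charges(s, q_neutral, origin = o)$mu_vec, ref_n,
                 tolerance = 1e-10)
    if (max(abs(dipole_from_charges(s, q_charged, origin = o)$mu_vec -
                ref_c)) > 1e-6) shifted <- TRUE
  }
  expect_true(shifted)  # nonzero total charge -> origin matters
})

test_that("assembly produces complete matrices and aggregates failures", {
  set.seed(45)
  lib1 <- gen_toy_structures("H", modifier_ids = "m1")
  m1 <- assemble_descriptors(lib1, list(descriptor_spec("bond_length", c(1, 7))))
  expect_equal(dim(m1), c(1L, 1L))
  expect_equal(attr(m1, "configuration"), "free_acid")

  frags <- c("H", "F", "Cl", "Br", "Me", "OH", "CN", "CF3", "NO2", "OMe")
  lib <- configuration_library("free_acid", c(
    gen_toy_structures(frags, modifier_ids = sprintf("BA%02d", 1:10))$structures,
    gen_toy_structures(frags[1:5], position = "meta",
                       modifier_ids = sprintf("BA%02d", 11:15))$structures))
  ch <- do.call(rbind, lapply(names(lib$structures), function(nm) {
    n <- n_atoms(lib$structures[[nm]])
    q <- rnorm(n, 0, 0.3)
    data.frame(structure = nm, atom_index = seq_len(n), charge = q - mean(q))
  }))
  fr <- data.frame(structure = names(lib$structures), mode = "B-O_stretch",
                   frequency_cm1 = rnorm(15, 1350, 25))
  ann <- read_annotations(ch, frequencies = fr, structures = lib)
  specs <- list(
    descriptor_spec("sterimol_L", c(1, 7), label = "L_B"),
    descriptor_spec("sterimol_B1", c(1, 7), label = "B1_B"),
    descriptor_spec("sterimol_B5", c(1, 7), label = "B5_B"),
    descriptor_spec("bond_length", c(1, 7), label = "d_CB"),
    descriptor_spec("bond_length", c(7, 8), label = "d_BO"),
    descriptor_spec("distance", c(4, 7), label = "d_para_B"),
    descriptor_spec("dihedral", c(2, 1, 7, 8), label = "phi_BOH"),
    descriptor_spec("charge", 7, label = "q_B"),
    descriptor_spec("charge_difference", c(8, 10), label = "dq_OO"),
    descriptor_spec("dipole_total", label = "mu_tot"),
    descriptor_spec("dipole_component", axis = "axis2", label = "mu_om"),
    descriptor_spec("frequency", mode = "B-O_stretch", label = "nu_BO"))
  m <- assemble_descriptors(lib, specs, annotations = ann, ring_atoms = 1:6)
  expect_equal(dim(m), c(15L, 12L))
  expect_false(anyNA(m))
  expect_equal(unname(attr(m, "units")[c("L_B", "phi_BOH", "q_B", "nu_BO")]),
               c("Angstrom", "degree", "e", "cm^-1"))

  # a spec referencing an absent atom fails with the modifier named
  bad <- c(specs, list(descriptor_spec("distance", c(1, 99), label = "d_bad")))
  expect_error(assemble_descriptors(lib, bad, annotations = ann,
                                    ring_atoms = 1:6),
               "BA01.*d_bad")
})

test_that("descriptor matrix CSV round-trips with units and provenance", {
  set.seed(46)
  m <- descriptor_matrix(matrix(rnorm(12), 3, 4,
                                dimnames = list(paste0("m", 1:3),
                                                paste0("d", 1:4))),
                         units = setNames(c("Angstrom", "e", "deg", "cm^-1"),
                                          paste0("d", 1:4)),
                         configuration = "pi_complex")
  f <- withr::local_tempfile(fileext = ".csv")
  write_descriptor_matrix(m, f)
  back <- read_descriptor_matrix(f)
  expect_equal(unclass(back), unclass(m), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(attr(back, "units"), attr(m, "units"))
  expect_equal(attr(back, "configuration"), "pi_complex")
  expect_equal(rownames(back), rownames(m))
})
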