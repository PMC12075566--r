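# Small reference molecules built in code.

make_benzene <- function() {
  ang <- 2 * pi * (0:5) / 6
  molecule3d("benzene", rep("C", 6),
             cbind(1.39 * cos(ang), 1.39 * sin(ang), 0),
             bonds = data.frame(from = 1:6, to = c(2:6, 1),
                                order = c(1, 2, 1, 2, 1, 2)))
}

make_methylammonium <- function() {
  molecule3d("methylammonium", c("C", "N", "H", "H", "H", "H", "H", "H"),
             rbind(c(0, 0, 0), c(1.5, 0, 0), c(-0.5, 0.9, 0), c(-0.5, -0.9, 0),
                   c(-0.5, 0, 0.9), c(2, 0.9, 0), c(2, -0.9, 0), c(2, 0, 0.9)),
             charges = c(0, 1, 0, 0, 0, 0, 0, 0),
             bonds = data.frame(from = c(1, 1, 1, 1, 2, 2, 2),
                                to = c(2, 3, 4, 5, 6, 7, 8), order = 1))
}

make_acetate <- function() {
  molecule3d("acetate", c("C", "C", "O", "O", "H", "H", "H"),
             rbind(c(0, 0, 0), c(1.5, 0, 0), c(2.2, 1.1, 0), c(2.2, -1.1, 0),
                   c(-0.5, 0.9, 0), c(-0.5, -0.9, 0), c(-0.5, 0, 0.9)),
             charges = c(0, 0, 0, -1, 0, 0, 0),
             bonds = data.frame(from = c(1, 2, 2, 1, 1, 1),
                                to = c(2, 3, 4, 5, 6, 7),
                                order = c(1, 2, 1, 1, 1, 1)))
}

# Feature set sitting exactly on a hypothesis' coordinates.
fs_on_hypothesis <- function(h, id = "exact") {
  feature_set(id, lapply(h$features, function(f)
    pharm_feature(f$ftype, f$position, direction = f$direction)))
}

# A simple 4-feature reference hypothesis.
make_ref_hypothesis <- function(tolerance = 1.0) {
  hypothesis("APRR-ref", list(
    pharm_feature("A", c(0, 0, 0), direction = c(0, 0, 1)),
    pharm_feature("P", c(5, 0, 0)),
    pharm_feature("R", c(2.5, 3, 1), direction = c(0, 0, 1)),
    pharm_feature("R", c(2.5, -3, 1), direction = c(0.2, 0, 1))),
    tolerance = tolerance)
}

# Minimal two-residue receptor for interaction typing tests.
make_interaction_receptor <- function() {
  data.frame(
    chain = "A",
    resno = c(569, 569, 100, 100, 100, 100),
    resname = c("ASP", "ASP", "POPC", "POPC", "POPC", "POPC"),
    atom = c("OD1", "OD2", "P", "O11", "O12", "C1"),
    element = c("O", "O", "P", "O", "O", "C"),
    x = c(0, 1.0, 20, 20.5, 19.5, 22),
    y = c(0, 0.8, 0, 1.0, -1.0, 0),
    z = 0, stringsAsFactors = FALSE)
}
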