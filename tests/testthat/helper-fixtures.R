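# Shared fixtures for the test suite. Everything is generated in code.

# clean rendering scenario: all spots doubly labeled, responsive, no bleach
clean_scenario <- function(...) {
  kinetic_scenario(frac_responsive = 1, frac_inactive = 0,
                   frac_donor_only = 0, frac_acceptor_only = 0,
                   bleach_rate_d = 0, bleach_rate_a = 0, ...)
}

default_cf <- function() correction_factors(lk = 0.08, dir = 0.05)

# ground truth with prescribed transition times (for deterministic cases)
manual_truth <- function(duration, initial_state, trans_times,
                         bleach_d = Inf, bleach_a = Inf,
                         spot_class = "pair") {
  structure(list(duration = duration, initial_state = initial_state,
                 trans_times = trans_times, bleach_d = bleach_d,
                 bleach_a = bleach_a, spot_class = spot_class),
            class = "ground_truth")
}

# minimal PDB text with C-alpha atoms at given coordinates; used to test
# structure-distance computations on files we construct ourselves
write_mini_pdb <- function(path, atoms) {
  # atoms: data.frame chain, resno, x, y, z
  lines <- vapply(seq_len(nrow(atoms)), function(i) {
    a <- atoms[i, ]
    sprintf("ATOM  %5d  CA  ALA %s%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
            i, a$chain, a$resno, a$x, a$y, a$z)
  }, character(1))
  writeLines(c(lines, "END"), path)
  path
}
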