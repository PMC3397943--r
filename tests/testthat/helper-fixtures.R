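# Fixture builders shared across the suite. Everything is generated in code;
# no binary or downloaded data.

pdb_line <- function(serial, name, resname, chain, resno, x, y, z,
                     occ = 1, b = 0, elem = NULL, record = "ATOM",
                     alt = " ", ins = " ") {
  if (is.null(elem)) elem <- substr(gsub("[0-9]", "", name), 1, 1)
  name4 <- if (nchar(name) < 4) sprintf(" %-3s", name) else name
  sprintf("%-6s%5d %4s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          record, serial, name4, alt, resname, chain, resno, ins,
          x, y, z, occ, b, elem)
}

# a minimal well-formed chain: `resnos` ALA-like residues with 5 heavy atoms
# each (N, CA, C, O, CB), laid out along x
write_test_pdb <- function(file, resnos = 1:3, chain = "A", het_lines = NULL,
                           extra_lines = NULL) {
  lines <- character(0)
  serial <- 0L
  offsets <- list(N = c(0, 0.5, 0), CA = c(0, 0, 0), C = c(0.8, 0, 0.4),
                  O = c(0.8, 0.9, 0.4), CB = c(0, -0.8, 0.9))
  for (k in seq_along(resnos)) {
    base <- c(3.8 * (k - 1), 0, 0)
    for (nm in names(offsets)) {
      serial <- serial + 1L
      p <- base + offsets[[nm]]
      lines <- c(lines, pdb_line(serial, nm, "ALA", chain, resnos[k],
                                 p[1], p[2], p[3]))
    }
  }
  lines <- c(lines, extra_lines, het_lines, "END")
  writeLines(lines, file)
  file
}

random_rotation <- function() {
  q <- rnorm(4)
  q <- q / sqrt(sum(q^2))
  a <- q[1]; b <- q[2]; c <- q[3]; d <- q[4]
  matrix(c(a^2 + b^2 - c^2 - d^2, 2 * (b * c - a * d), 2 * (b * d + a * c),
           2 * (b * c + a * d), a^2 - b^2 + c^2 - d^2, 2 * (c * d - a * b),
           2 * (b * d - a * c), 2 * (c * d + a * b), a^2 - b^2 - c^2 + d^2),
         3, 3, byrow = TRUE)
}

# coordset with n members around given base coordinates (N x 3) plus noise
noisy_coordset <- function(base, n, sigma, states = "APO") {
  coords <- t(vapply(seq_len(n), function(i)
    as.numeric(t(base)) + rnorm(length(base), 0, sigma),
    numeric(length(base))))
  new_coordset(labels = as.character(seq_len(nrow(base))), coords = coords,
               state = states)
}

# exact two-sided Fisher p for a 2x2 contact table, by hypergeometric
# enumeration (independent of stats::fisher.test)
fisher_enum_p <- function(a, nA, b, nB) {
  t <- a + b
  xs <- max(0, t - nB):min(nA, t)
  probs <- dhyper(xs, t, nA + nB - t, nA)
  p_obs <- dhyper(a, t, nA + nB - t, nA)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# brute-force residue-probe contact oracle: double loop over heavy atoms
contact_oracle <- function(s, ps, cutoff) {
  a <- s$atoms[!s$atoms$het, , drop = FALSE]
  labs <- unique(paste0(a$resno, a$ins))
  out <- setNames(integer(length(labs)), labs)
  for (p in ps$probes) {
    for (i in seq_len(nrow(a))) {
      for (j in seq_len(nrow(p$coords))) {
        d <- sqrt(sum((c(a$x[i], a$y[i], a$z[i]) - p$coords[j, ])^2))
        if (d < cutoff) out[paste0(a$resno[i], a$ins[i])] <- 1L
      }
    }
  }
  out
}

# helix-backbone structure with 5 heavy atoms per residue (N, CA, C, O, CB),
# the standard fixture for SASA convergence and timing checks
multi_atom_structure <- function(n_res, seed = 2) {
  sp <- synthetic_spec(n_residues = n_res, n_per_state = c(1, 1),
                       sigma = 0, seed = seed)
  cs <- make_two_state_ensemble(sp)
  ca <- matrix(cs$coords[1, ], ncol = 3, byrow = TRUE)
  offs <- rbind(c(0, 0.5, 0), c(0, 0, 0), c(0.8, 0, 0.4),
                c(0.8, 0.9, 0.4), c(0, -0.8, 0.9))
  xyz <- do.call(rbind, lapply(seq_len(n_res), function(k)
    sweep(offs, 2, ca[k, ], `+`)))
  atoms <- data.frame(
    elety = rep(c("N", "CA", "C", "O", "CB"), n_res),
    elem = rep(c("N", "C", "C", "O", "C"), n_res),
    resid = "ALA", resno = rep(seq_len(n_res), each = 5), ins = "",
    chain = "A", x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    b = 0, o = 1, het = FALSE, stringsAsFactors = FALSE)
  structure(list(id = "fix", atoms = atoms, het_codes = character(0)),
            class = "structure3d")
}
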