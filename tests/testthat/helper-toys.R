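## Builders for small hand-constructed systems and independent oracles used
## across the suite.  Everything is generated in code; no stored fixtures.

toy_topology <- function(df, xyz, box = c(50, 50, 50)) {
  df$is_hydrogen <- df$is_hydrogen %||% rep(FALSE, nrow(df))
  lipidsite:::new_topology(
    data.frame(name = df$name, resid = df$resid, resname = df$resname,
               chain = df$chain, is_hydrogen = df$is_hydrogen,
               mol_class = df$mol_class, stringsAsFactors = FALSE),
    xyz, box)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

one_frame_traj <- function(xyz, box, time = 0) {
  trajectory_memory(list(list(xyz = xyz, box = box, time = time)))
}

## random small protein + lipid system for oracle-equivalence checks
random_contact_system <- function(seed, n_prot_res = 4, n_lip = 6,
                                  box = c(30, 30, 30)) {
  set.seed(seed)
  chains <- sample(c("A", "B"), n_prot_res, replace = TRUE)
  prot <- do.call(rbind, lapply(seq_len(n_prot_res), function(i) {
    k <- sample(1:3, 1)
    data.frame(name = paste0("B", seq_len(k)), resid = 100 + i,
               resname = "ALA", chain = chains[i],
               mol_class = "protein")
  }))
  lip <- data.frame(name = "NC3", resid = 1000 + seq_len(n_lip),
                    resname = "POPC", chain = "U", mol_class = "lipid_PC")
  df <- rbind(prot, lip)
  xyz <- matrix(runif(3 * nrow(df), 0, box[1]), ncol = 3)
  list(top = toy_topology(df, xyz, box), n_prot = nrow(prot))
}

random_frames <- function(top, n, seed) {
  set.seed(seed)
  trajectory_memory(lapply(seq_len(n), function(i)
    list(xyz = matrix(runif(3 * n_particles(top), 0, top$box[1]), ncol = 3),
         box = top$box, time = i)))
}

## Independent brute-force contact profile: plain loops over residues,
## frames, particles; scalar min_image_distance only.
oracle_contact_profile <- function(traj, top, head_sel, thr, frames = NULL) {
  p <- top$particles
  head_idx <- which(p$name %in% head_sel$atom_names &
                    as.character(p$mol_class) %in% head_sel$mol_class)
  prot_idx <- which(p$mol_class == "protein")
  keys <- unique(paste(p$chain[prot_idx], p$resid[prot_idx]))
  keys <- keys[order(keys)]
  if (is.null(frames)) frames <- seq_len(n_frames(traj))
  freq <- setNames(numeric(length(keys)), keys)
  for (fi in frames) {
    f <- get_frame(traj, fi)
    for (ki in seq_along(keys)) {
      parts <- strsplit(keys[ki], " ")[[1]]
      rows <- prot_idx[p$chain[prot_idx] == parts[1] &
                       p$resid[prot_idx] == as.integer(parts[2])]
      hit <- FALSE
      for (r in rows) {
        for (h in head_idx) {
          if (min_image_distance(f$xyz[r, ], f$xyz[h, ], f$box) <= thr) {
            hit <- TRUE; break
          }
        }
        if (hit) break
      }
      freq[ki] <- freq[ki] + hit
    }
  }
  freq / length(frames)
}

random_rotation <- function() {
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

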