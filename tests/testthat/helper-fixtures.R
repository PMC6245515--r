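# shared fixture helpers: tiny alignments, contact sets, rigid motions

write_tmp_fasta <- function(seqs, ids = paste0("s", seq_along(seqs))) {
  path <- tempfile(fileext = ".fasta")
  writeLines(paste0(">", ids, "\n", seqs), path)
  path
}

empty_contacts <- function() {
  structure(data.frame(i = integer(), j = integer(), score = numeric()),
            class = c("contact_set", "data.frame"))
}

contacts_from_df <- function(df) {
  structure(df, class = c("contact_set", "data.frame"))
}

# random rigid motion of an n x 3 coordinate set
rigid_transform <- function(X, seed = 1) {
  set.seed(seed)
  ang <- runif(3, 0, 2 * pi)
  Rz <- function(t) matrix(c(cos(t), -sin(t), 0, sin(t), cos(t), 0,
                             0, 0, 1), 3, 3)
  Rx <- function(t) matrix(c(1, 0, 0, 0, cos(t), -sin(t),
                             0, sin(t), cos(t)), 3, 3)
  R <- Rz(ang[1]) %*% Rx(ang[2]) %*% Rz(ang[3])
  X %*% R + matrix(runif(3, -5, 5), nrow(X), 3, byrow = TRUE)
}
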