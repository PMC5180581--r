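# Independent brute-force oracles and small fixtures, built in code.

# exhaustive window-scan gene finder: slide one character at a time, accept a
# gene at every promoter hit, then jump past it (first promoter wins)
brute_scan <- function(genome, anatomy = gene_anatomy()) {
  strings <- genome_strings(genome)
  np <- nchar(anatomy$promoter)
  gene_len <- np + anatomy$type_len + anatomy$binding_len + anatomy$payload_len
  out <- list()
  for (ci in seq_along(strings)) {
    s <- strings[ci]
    pos <- 1L
    while (pos + gene_len - 1L <= nchar(s)) {
      if (substr(s, pos, pos + np - 1L) == anatomy$promoter) {
        type_str <- substr(s, pos + np, pos + np + anatomy$type_len - 1L)
        tcode <- digits_of(type_str, genome$alphabet)
        code <- 0
        for (d in tcode) code <- code * length(genome$alphabet) + d
        site <- substr(s, pos + np + anatomy$type_len,
                       pos + np + anatomy$type_len + anatomy$binding_len - 1L)
        payload <- substr(s, pos + np + anatomy$type_len + anatomy$binding_len,
                          pos + gene_len - 1L)
        out[[length(out) + 1L]] <- data.frame(
          chromosome = ci, start = pos,
          gene_type = c("signalling", "regulatory", "structural")[code %% 3 + 1],
          binding_site = site, payload = payload)
        pos <- pos + gene_len
      } else {
        pos <- pos + 1L
      }
    }
  }
  if (length(out) == 0L) {
    return(data.frame(chromosome = integer(0), start = integer(0),
                      gene_type = character(0), binding_site = character(0),
                      payload = character(0)))
  }
  do.call(rbind, out)
}

digits_of <- function(s, alphabet) {
  match(strsplit(s, "", fixed = TRUE)[[1]], alphabet) - 1L
}

# count complement mismatches character by character
brute_mismatches <- function(sig, site, alphabet = c("0", "1", "2", "3")) {
  a <- digits_of(sig, alphabet)
  b <- digits_of(site, alphabet)
  sum(a != (length(alphabet) - 1L) - b)
}

# count robots/food around a position by looping over every grid cell
brute_neighbourhood <- function(world, pos, radius = 1L) {
  n <- world$size
  fm <- grnswarm:::food_matrix(world)
  robots <- 0L
  food <- 0L
  for (x in seq_len(n)) for (y in seq_len(n)) {
    dx <- abs(x - pos[1L]); dy <- abs(y - pos[2L])
    if (world$torus) {
      dx <- min(dx, n - dx); dy <- min(dy, n - dy)
    }
    if (max(dx, dy) <= radius) {
      robots <- robots + world$occ[x, y]
      food <- food + fm[x, y]
    }
  }
  robots <- robots - min(world$occ[pos[1L], pos[2L]], 1L)
  c(robots = robots, food = food)
}

# a chromosome string with a single gene at a chosen offset and no other
# promoter occurrence ("2" never starts the default promoter "0101")
single_gene_chromosome <- function(offset, type = "signalling",
                                   site = "0000", payload = "22222222",
                                   total = 60L) {
  type_field <- switch(type, signalling = "00", regulatory = "01",
                       structural = "02")
  gene <- paste0("0101", type_field, site, payload)
  lead <- strrep("2", offset - 1L)
  tail_len <- total - (offset - 1L) - nchar(gene)
  stopifnot(tail_len >= 0L)
  paste0(lead, gene, strrep("2", tail_len))
}

genome_from_strings <- function(strings, alphabet = c("0", "1", "2", "3")) {
  tmp <- tempfile()
  writeLines(c(paste0("# alphabet: ", paste(alphabet, collapse = "")),
               strings), tmp)
  on.exit(unlink(tmp))
  read_genome(tmp)
}

# compact study conditions for engine tests: small grid, short genomes,
# few robots, low extinction line
small_config <- function(...) {
  base <- default_config(
    world = list(size = 18L),
    genome = list(n_chromosomes = 3L, chrom_length = 3000L),
    food = list(types = data.frame(threshold = c(0, 30, 60),
                                   energy = c(30, 60, 120),
                                   initial = c(15L, 10L, 10L))),
    population = list(initial = 30L, initial_energy = 60, extinction = 5L),
    sim = list(max_steps = 60L))
  overrides <- list(...)
  if (length(overrides) > 0L) base <- grnswarm:::merge_config(base, overrides)
  base
}
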