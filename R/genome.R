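# Artificial genome: a heritable string of digits over a 4-letter alphabet
# with complement pairing (0<->3, 1<->2, i.e. digit d pairs with 3 - d).
# Genes are laid out as promoter | type field | binding site | payload; the
# payload carries the gene product's signature and, for structural genes, the
# actuator index and output value.

GENE_TYPES <- c("signalling", "regulatory", "structural")

#' Create a random artificial genome
#'
#' The default genome is 10 chromosomes of 10,000 uniformly random characters
#' over the digit alphabet `{"0","1","2","3"}`. Characters are stored
#' internally as raw digit values; [genome_strings()] and [write_genome()]
#' expose the character representation.
#'
#' @param seed optional integer; when supplied, `set.seed(seed)` is called so
#'   that the same seed always yields a bit-identical genome. When `NULL` the
#'   current RNG stream is consumed (this is what the simulation engine does).
#' @param n_chromosomes number of chromosomes (>= 1).
#' @param chrom_length characters per chromosome (>= 1).
#' @param alphabet character vector of distinct single characters (>= 2
#'   letters). Complement pairing is positional: letter `i` pairs with letter
#'   `n - 1 - i`.
#' @return an object of class `artificial_genome` with elements
#'   `chromosomes` (list of raw vectors holding digit values), `alphabet`,
#'   and `provenance` (seed and cumulative mutation count).
#' @examples
#' g <- init_genome(seed = 1, n_chromosomes = 2, chrom_length = 100)
#' nchar(genome_strings(g)[1])
#' @export
init_genome <- function(seed = NULL, n_chromosomes = 10L, chrom_length = 10000L,
                        alphabet = c("0", "1", "2", "3")) {
  n_chromosomes <- as.integer(n_chromosomes)
  chrom_length <- as.integer(chrom_length)
  if (is.na(n_chromosomes) || n_chromosomes < 1L)
    stop_invalid("n_chromosomes must be a positive integer")
  if (is.na(chrom_length) || chrom_length < 1L)
    stop_invalid("chrom_length must be a positive integer")
  if (length(alphabet) < 2L || anyDuplicated(alphabet) ||
      any(nchar(alphabet) != 1L))
    stop_invalid("alphabet must hold at least two distinct single characters")
  if (!is.null(seed)) set.seed(as.integer(seed))
  k <- length(alphabet)
  chroms <- lapply(seq_len(n_chromosomes), function(i) {
    as.raw(sample.int(k, chrom_length, replace = TRUE) - 1L)
  })
  structure(list(chromosomes = chroms, alphabet = alphabet,
                 provenance = list(seed = seed, mutations = 0L)),
            class = "artificial_genome")
}

#' @export
print.artificial_genome <- function(x, ...) {
  lens <- vapply(x$chromosomes, length, 0L)
  cat("artificial_genome:", length(lens), "chromosome(s),",
      sum(lens), "characters, alphabet {",
      paste(x$alphabet, collapse = ","), "},",
      x$provenance$mutations, "mutation(s)\n")
  invisible(x)
}

# chromosomes as integer digit vectors
genome_ints <- function(genome) lapply(genome$chromosomes, as.integer)

#' Chromosomes as character strings
#' @param genome an `artificial_genome`.
#' @return character vector, one string per chromosome.
#' @export
genome_strings <- function(genome) {
  vapply(genome$chromosomes, function(v) {
    paste(genome$alphabet[as.integer(v) + 1L], collapse = "")
  }, "")
}

string_to_raw <- function(s, alphabet) {
  idx <- match(strsplit(s, "", fixed = TRUE)[[1]], alphabet)
  if (anyNA(idx)) stop_invalid("chromosome contains characters outside the alphabet")
  as.raw(idx - 1L)
}

#' Gene-anatomy parameters
#'
#' Bundles the layout constants used when scanning a genome for genes:
#' the promoter motif, the width of the type field, the binding-site length
#' and the payload length. The payload encodes a product signature of
#' `binding_len` characters followed by four characters that set the
#' regulatory mode (activation/repression) or, for structural genes, the
#' actuator index and output value.
#'
#' @param promoter promoter motif (string over the alphabet).
#' @param type_len width of the type field in characters.
#' @param binding_len binding-site (and signature) length.
#' @param payload_len payload length; must be at least `binding_len + 4`.
#' @param match_tolerance maximum complement mismatches for a binding match.
#' @return a list of class `gene_anatomy`.
#' @export
gene_anatomy <- function(promoter = "0101", type_len = 2L, binding_len = 4L,
                         payload_len = 8L, match_tolerance = 1L) {
  payload_len <- as.integer(payload_len)
  binding_len <- as.integer(binding_len)
  if (payload_len < binding_len + 4L)
    stop_invalid("payload_len must be at least binding_len + 4")
  if (match_tolerance < 0L || match_tolerance > binding_len)
    stop_invalid("match_tolerance must lie in [0, binding_len]")
  structure(list(promoter = promoter, type_len = as.integer(type_len),
                 binding_len = binding_len, payload_len = payload_len,
                 match_tolerance = as.integer(match_tolerance)),
            class = "gene_anatomy")
}

anatomy_from_config <- function(config) {
  g <- config$genome
  gene_anatomy(g$promoter, g$type_len, g$binding_len, g$payload_len,
               g$match_tolerance)
}

#' Scan a genome for gene loci
#'
#' Finds every gene, left to right within each chromosome. A gene starts at a
#' promoter motif occurrence; once a promoter is accepted, scanning resumes
#' after the full gene, so promoter hits overlapping an accepted gene are
#' skipped ("first promoter wins"). A promoter too close to the chromosome
#' end to fit a complete gene is ignored. Scanning is pure: the genome is
#' never modified.
#'
#' @param genome an `artificial_genome`.
#' @param anatomy a [gene_anatomy()]; defaults to the package defaults.
#' @return a data.frame sorted by (chromosome, start) with one row per locus:
#'   `chromosome` (1-based index), `start`, `end` (1-based inclusive
#'   character positions of the whole gene), `promoter` (offset of the
#'   promoter = `start`), `gene_type` (signalling/regulatory/structural),
#'   `binding_site` and `payload` (character), plus numeric codes used by the
#'   controller: `sig_code`, `site_code` (base-k codes of signature and
#'   binding site), `mode` (0 activator / 1 repressor), `actuator` (1-based
#'   index, structural genes only, otherwise NA) and `value` (output value in
#'   [0, 1], structural genes only, otherwise NA).
#' @export
scan_genes <- function(genome, anatomy = gene_anatomy()) {
  sc <- scan_codes(genome, anatomy)
  n <- length(sc$start)
  gene_len <- nchar(anatomy$promoter) + anatomy$type_len +
    anatomy$binding_len + anatomy$payload_len
  code_str <- function(code, len) {
    vapply(code, function(cd) {
      paste(genome$alphabet[code_to_digits(cd, length(genome$alphabet),
                                           len) + 1L], collapse = "")
    }, "")
  }
  is_struct <- sc$type_idx == 2L
  out <- data.frame(
    chromosome = sc$chromosome, start = sc$start,
    end = sc$start + gene_len - 1L, promoter = sc$start,
    gene_type = GENE_TYPES[sc$type_idx + 1L],
    binding_site = code_str(sc$site_code, anatomy$binding_len),
    payload = code_str(sc$payload_code, anatomy$payload_len),
    sig_code = sc$sig_code, site_code = sc$site_code,
    mode = sc$mode,
    actuator = ifelse(is_struct, sc$actuator, NA_integer_),
    value = ifelse(is_struct, sc$value, NA_real_))
  rownames(out) <- NULL
  out
}

# integer-code scan (the hot path behind scan_genes and genome_tables):
# locates genes and decodes their fields without any string work
scan_codes <- function(genome, anatomy) {
  k <- length(genome$alphabet)
  pro <- as.integer(string_to_raw(anatomy$promoter, genome$alphabet))
  np <- length(pro)
  tl <- anatomy$type_len
  lb <- anatomy$binding_len
  lp <- anatomy$payload_len
  gene_len <- np + tl + lb + lp
  chrom <- integer(0); starts_all <- integer(0)
  vs <- vector("list", length(genome$chromosomes))
  for (ci in seq_along(genome$chromosomes)) {
    v <- as.integer(genome$chromosomes[[ci]])
    vs[[ci]] <- v
    n <- length(v)
    if (n < gene_len) next
    # all (possibly overlapping) promoter occurrences
    ok <- v[seq_len(n - np + 1L)] == pro[1L]
    if (np > 1L) for (j in 2L:np) {
      ok <- ok & v[j:(n - np + j)] == pro[j]
    }
    cand <- which(ok)
    if (length(cand) == 0L) next
    # greedy left-to-right: accept a promoter, skip anything inside the gene
    starts <- integer(0)
    last_end <- 0L
    for (p in cand) {
      if (p > last_end && p + gene_len - 1L <= n) {
        starts <- c(starts, p)
        last_end <- p + gene_len - 1L
      }
    }
    if (length(starts) > 0L) {
      chrom <- c(chrom, rep.int(ci, length(starts)))
      starts_all <- c(starts_all, starts)
    }
  }
  n <- length(starts_all)
  empty <- list(chromosome = integer(0), start = integer(0),
                type_idx = integer(0), site_code = integer(0),
                sig_code = integer(0), payload_code = numeric(0),
                mode = integer(0), actuator = integer(0), value = numeric(0))
  if (n == 0L) return(empty)
  # gather field digits across chromosomes in one pass
  field <- function(off, len) {
    m <- matrix(0L, n, len)
    for (ci in unique(chrom)) {
      sel <- chrom == ci
      st <- starts_all[sel]
      for (j in seq_len(len)) m[sel, j] <- vs[[ci]][st + off + j - 1L]
    }
    m
  }
  codes <- function(m) {
    out <- numeric(nrow(m))
    for (j in seq_len(ncol(m))) out <- out * k + m[, j]
    out
  }
  tcode <- codes(field(np, tl))
  site <- codes(field(np + tl, lb))
  pay <- field(np + tl + lb, lp)
  sig <- codes(pay[, seq_len(lb), drop = FALSE])
  e <- pay[, lb + (1:4), drop = FALSE]
  type_idx <- as.integer(tcode %% 3)
  list(chromosome = chrom, start = starts_all, type_idx = type_idx,
       site_code = as.integer(site), sig_code = as.integer(sig),
       payload_code = codes(pay),
       mode = ifelse(type_idx == 1L, e[, 1L] %% 2L, 0L),
       actuator = as.integer((k * e[, 1L] + e[, 2L]) %% length(ACTUATORS) + 1L),
       value = as.numeric(2 * (k * e[, 3L] + e[, 4L]) >= k * k))
}

#' Does a product signature bind a binding site?
#'
#' A signature binds a site when the character-wise complement distance —
#' the number of positions at which the signature differs from the site's
#' complement — is at most `tolerance`. Complementation is positional over
#' the alphabet: letter `i` pairs with letter `n - 1 - i` (so for the default
#' digits, 0 with 3 and 1 with 2).
#'
#' @param signature,binding_site equal-length character sequences over
#'   `alphabet`.
#' @param tolerance maximum number of complement mismatches (default 1).
#' @param alphabet the genome alphabet.
#' @return `TRUE` if the signature binds the site.
#' @examples
#' binds("0123", "3210", tolerance = 0)  # perfect complement
#' binds("0123", "0123", tolerance = 0)  # identity is not complementarity
#' @export
binds <- function(signature, binding_site, tolerance = 1L,
                  alphabet = c("0", "1", "2", "3")) {
  s <- string_to_raw(signature, alphabet)
  b <- string_to_raw(binding_site, alphabet)
  if (length(s) != length(b))
    stop_invalid("signature and binding_site must have equal length")
  complement_mismatches(as.integer(s), as.integer(b), length(alphabet)) <=
    tolerance
}

complement_mismatches <- function(sig_digits, site_digits, k) {
  sum(sig_digits != (k - 1L) - site_digits)
}

#' Mutation-rate parameters
#'
#' @param point_rate probability per character per replication of a point
#'   mutation (the character is always replaced by a different letter).
#' @param duplication_rate probability per chromosome per replication of a
#'   segmental duplication.
#' @param duplication_mean_len mean duplicated-segment length (geometric).
#' @return a list of class `mutation_rates`.
#' @export
mutation_rates <- function(point_rate = 0.001, duplication_rate = 0.01,
                           duplication_mean_len = 50) {
  if (point_rate < 0 || point_rate > 1 || duplication_rate < 0 ||
      duplication_rate > 1)
    stop_invalid("mutation probabilities must lie in [0, 1]")
  if (duplication_mean_len < 1)
    stop_invalid("duplication_mean_len must be >= 1")
  structure(list(point_rate = point_rate, duplication_rate = duplication_rate,
                 duplication_mean_len = duplication_mean_len),
            class = "mutation_rates")
}

#' Replicate a genome with mutation
#'
#' Produces a child genome: every character independently suffers a point
#' mutation with probability `rates$point_rate` (mutations always change the
#' character, resampling uniformly from the other letters), and each
#' chromosome independently undergoes a segmental duplication with
#' probability `rates$duplication_rate` (a contiguous segment of geometric
#' length, mean `duplication_mean_len`, is copied from a uniform source
#' position and inserted at a uniform insertion point of the same
#' chromosome). With all rates zero the child is identical to the parent.
#'
#' @param parent an `artificial_genome`.
#' @param rates a [mutation_rates()] object.
#' @param seed optional integer seed (`NULL`: consume the current RNG stream).
#' @return the child `artificial_genome`.
#' @export
replicate_genome <- function(parent, rates = mutation_rates(), seed = NULL) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  k <- length(parent$alphabet)
  nmut_total <- 0L
  chroms <- lapply(parent$chromosomes, function(ch) {
    v <- as.integer(ch)
    L <- length(v)
    nmut <- rbinom(1L, L, rates$point_rate)
    if (nmut > 0L) {
      pos <- sample.int(L, nmut)
      shift <- sample.int(k - 1L, nmut, replace = TRUE)
      v[pos] <- (v[pos] + shift) %% k
      nmut_total <<- nmut_total + nmut
    }
    if (rates$duplication_rate > 0 && runif(1L) < rates$duplication_rate) {
      len <- 1L + rgeom(1L, 1 / rates$duplication_mean_len)
      len <- min(len, L)
      src <- sample.int(L - len + 1L, 1L)
      ins <- sample.int(L + 1L, 1L) - 1L  # insert after position `ins`
      seg <- v[src:(src + len - 1L)]
      v <- append(v, seg, after = ins)
      nmut_total <<- nmut_total + 1L
    }
    as.raw(v)
  })
  structure(list(chromosomes = chroms, alphabet = parent$alphabet,
                 provenance = list(seed = parent$provenance$seed,
                                   mutations = parent$provenance$mutations +
                                     nmut_total)),
            class = "artificial_genome")
}

#' Write / read a genome as plain text
#'
#' Format: a header line `# alphabet: <letters>` followed by one chromosome
#' per line. Round-tripping is bit-exact.
#'
#' @param genome an `artificial_genome`.
#' @param path file path.
#' @return `write_genome` returns `path` invisibly; `read_genome` returns the
#'   genome.
#' @export
write_genome <- function(genome, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# alphabet: ", paste(genome$alphabet, collapse = "")), con)
  writeLines(genome_strings(genome), con)
  invisible(path)
}

#' @rdname write_genome
#' @export
read_genome <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 2L || !startsWith(lines[1L], "# alphabet: "))
    stop_invalid("not a genome file: missing alphabet header")
  alphabet <- strsplit(sub("^# alphabet: ", "", lines[1L]), "", fixed = TRUE)[[1]]
  chroms <- lapply(lines[-1L], string_to_raw, alphabet = alphabet)
  structure(list(chromosomes = chroms, alphabet = alphabet,
                 provenance = list(seed = NA, mutations = NA)),
            class = "artificial_genome")
}

# ---- binding lookup tables -------------------------------------------------
# For the default anatomy (4 letters, binding length 4) all signatures and
# sites live in a 256-code space; complement-mismatch counts between codes are
# precomputed once and cached, which makes per-genome wiring a table lookup.

mismatch_table <- function(k, len) {
  key <- paste0("mm_", k, "_", len)
  tab <- .grnswarm_env[[key]]
  if (!is.null(tab)) return(tab)
  ncodes <- k^len
  digs <- matrix(0L, ncodes, len)
  codes <- 0:(ncodes - 1)
  for (j in len:1) {
    digs[, j] <- codes %% k
    codes <- codes %/% k
  }
  tab <- matrix(0L, ncodes, ncodes)
  for (j in seq_len(len)) {
    tab <- tab + outer(digs[, j], (k - 1L) - digs[, j], "!=")
  }
  storage.mode(tab) <- "integer"
  .grnswarm_env[[key]] <- tab
  tab
}

# list: for each signature code (1-indexed by code+1), the site codes it binds
match_codes <- function(k, len, tolerance) {
  key <- paste0("mc_", k, "_", len, "_", tolerance)
  ml <- .grnswarm_env[[key]]
  if (!is.null(ml)) return(ml)
  mm <- mismatch_table(k, len)
  ml <- lapply(seq_len(nrow(mm)), function(i) which(mm[i, ] <= tolerance) - 1L)
  .grnswarm_env[[key]] <- ml
  ml
}
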