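#' Animat genomes and hidden Markov gate (HMG) encoding
#'
#' An animat genome is a vector of integer loci in \code{[0, 255]} with length
#' between 1,000 and 20,000. Each occurrence of the start codon (consecutive
#' loci 42, 213) marks a gene encoding one hidden Markov gate: a deterministic
#' logic gate with 1--4 inputs drawn from the sensors and hidden elements and
#' 1--4 outputs writing to the hidden elements and motors.
#'
#' The gene layout is: codon (2 loci), one locus each for the input and output
#' counts (\code{n = 1 + locus \%\% 4}), 4 input-address loci, 4 output-address
#' loci, and 16 table loci (always reserved for the maximal 2^4 rows, of which
#' the first \code{2^n_inputs} are active, so that mutations changing the
#' input count only add or remove table rows). Addresses map modulo 6 onto the
#' legal input elements (2 sensors + 4 hidden) and output elements (4 hidden +
#' 2 motors). The genome is read circularly, so genes inserted near the end
#' wrap around the origin.
#'
#' @name genome
NULL

GENOME_MIN <- 1000L
GENOME_MAX <- 20000L

validate_genome <- function(genome) {
  if (!is.numeric(genome)) stop("genome must be an integer vector")
  genome <- as.integer(genome)
  if (length(genome) < GENOME_MIN || length(genome) > GENOME_MAX)
    stop("genome length must be in [", GENOME_MIN, ", ", GENOME_MAX, "]")
  if (anyNA(genome) || any(genome < 0L) || any(genome > 255L))
    stop("genome loci must be integers in [0, 255]")
  genome
}

#' Ancestral genome
#'
#' The generation-zero genome: all loci zero, so it contains no start codon,
#' decodes to no gates, and yields a brain without any connections.
#'
#' @param length Number of loci (between 1,000 and 20,000).
#' @return Integer vector of zero loci.
#' @export
ancestral_genome <- function(length = 5000L) {
  length <- as.integer(length)
  if (length < GENOME_MIN || length > GENOME_MAX)
    stop("length must be in [", GENOME_MIN, ", ", GENOME_MAX, "]")
  integer(length)
}

#' Random genome
#'
#' Uniform random loci; used for fuzz tests, not for evolution (evolution
#' starts from [ancestral_genome()]).
#'
#' @param length Number of loci.
#' @return Integer vector of loci in \code{[0, 255]}.
#' @export
random_genome <- function(length = 5000L) {
  length <- as.integer(length)
  if (length < GENOME_MIN || length > GENOME_MAX)
    stop("length must be in [", GENOME_MIN, ", ", GENOME_MAX, "]")
  sample(0:255, length, replace = TRUE)
}

#' Decode a genome into gate specifications
#'
#' Scans the (circular) genome for start codons and decodes one hidden Markov
#' gate per occurrence. Decoding is a pure function of the loci; overlapping
#' genes each decode independently.
#'
#' @param genome Integer vector of loci.
#' @return List of gates; each gate is a list with elements \code{inputs}
#'   (1-based element indices, sorted; sensors 1--2, hidden 3--6),
#'   \code{outputs} (hidden 3--6, motors 7--8), and \code{table} (integer
#'   vector of \code{2^n_inputs} output bit-patterns; bit \code{k} of a
#'   pattern drives \code{outputs[k + 1]}). Table row \code{r} (0-based)
#'   corresponds to the input pattern whose bit \code{k} is the state of
#'   \code{inputs[k + 1]}.
#' @export
decode_genome <- function(genome) {
  genome <- validate_genome(genome)
  gates <- cpp_decode_genome(genome)
  lapply(gates, function(g) {
    gate_spec(g$inputs + 1L, g$outputs + 1L, g$table)
  })
}

#' Construct a gate specification
#'
#' @param inputs 1-based element indices the gate reads (sensors 1--2 or
#'   hidden 3--6); 1 to 4 of them, duplicates allowed.
#' @param outputs 1-based element indices the gate writes (hidden 3--6 or
#'   motors 7--8); 1 to 4 of them.
#' @param table Integer vector of length \code{2^length(inputs)}; entry
#'   \code{r + 1} is the output bit-pattern for input pattern \code{r}.
#' @return A \code{gate_spec} object.
#' @export
gate_spec <- function(inputs, outputs, table) {
  inputs <- sort(as.integer(inputs))
  outputs <- sort(as.integer(outputs))
  if (length(inputs) < 1 || length(inputs) > 4)
    stop("gates have 1 to 4 inputs")
  if (length(outputs) < 1 || length(outputs) > 4)
    stop("gates have 1 to 4 outputs")
  if (any(inputs < 1L | inputs > 6L))
    stop("gate inputs must come from sensors or hidden elements (1-6)")
  if (any(outputs < 3L | outputs > 8L))
    stop("gate outputs must go to hidden elements or motors (3-8)")
  table <- as.integer(table)
  if (length(table) != 2^length(inputs))
    stop("table must have 2^n_inputs rows")
  if (any(table < 0L) || any(table >= 2^length(outputs)))
    stop("table entries must be output bit-patterns in [0, 2^n_outputs)")
  structure(list(inputs = inputs, outputs = outputs, table = table),
            class = "gate_spec")
}

#' Mutation configuration
#'
#' Default rates follow the genetic algorithm used throughout: point
#' mutations with probability 0.5\% per locus (the locus is replaced by a
#' uniform random integer in \code{[0, 255]}), a deletion of 16--512 adjacent
#' loci with probability 2\% per genome, and a duplication of 16--512 adjacent
#' loci (inserted at a random position) with probability 5\%. Deletions and
#' duplications that would push the genome outside \code{[1000, 20000]} loci
#' are suppressed.
#'
#' @param point_rate Per-locus point mutation probability.
#' @param deletion_prob Per-genome deletion probability.
#' @param duplication_prob Per-genome duplication probability.
#' @param fragment_len_range Length-2 integer range of fragment sizes.
#' @param genome_len_range Length-2 integer range of admissible genome sizes.
#' @return A \code{mutation_config} object.
#' @export
mutation_config <- function(point_rate = 0.005, deletion_prob = 0.02,
                            duplication_prob = 0.05,
                            fragment_len_range = c(16L, 512L),
                            genome_len_range = c(1000L, 20000L)) {
  probs <- c(point_rate, deletion_prob, duplication_prob)
  if (any(!is.finite(probs)) || any(probs < 0) || any(probs > 1))
    stop("mutation probabilities must lie in [0, 1]")
  fragment_len_range <- as.integer(fragment_len_range)
  genome_len_range <- as.integer(genome_len_range)
  if (fragment_len_range[1] > fragment_len_range[2] ||
      fragment_len_range[1] < 1L)
    stop("invalid fragment length range")
  structure(list(point_rate = point_rate, deletion_prob = deletion_prob,
                 duplication_prob = duplication_prob,
                 fragment_len_range = fragment_len_range,
                 genome_len_range = genome_len_range),
            class = "mutation_config")
}

#' Mutate a genome
#'
#' Applies, in order, point mutations, one possible deletion, and one
#' possible duplication, drawing from R's random number stream (seed with
#' [set.seed()] for reproducibility).
#'
#' @param genome Integer vector of loci.
#' @param config A [mutation_config()].
#' @return The mutated genome (integer vector).
#' @export
mutate_genome <- function(genome, config = mutation_config()) {
  genome <- validate_genome(genome)
  if (!inherits(config, "mutation_config")) stop("config must be a mutation_config")
  cpp_mutate(genome, config$point_rate, config$deletion_prob,
             config$duplication_prob,
             config$fragment_len_range[1], config$fragment_len_range[2],
             config$genome_len_range[1], config$genome_len_range[2])
}

#' Read and write genomes as text
#'
#' One genome per line, comma-separated loci.
#'
#' @param genomes List of genomes (integer vectors).
#' @param path File path.
#' @return \code{read_genomes} returns a list of integer vectors.
#' @export
write_genomes <- function(genomes, path) {
  if (is.numeric(genomes)) genomes <- list(genomes)
  lines <- vapply(genomes, function(g) paste(as.integer(g), collapse = ","),
                  character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_genomes
#' @export
read_genomes <- function(path) {
  lines <- readLines(path)
  lapply(lines, function(l) as.integer(strsplit(l, ",", fixed = TRUE)[[1]]))
}
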