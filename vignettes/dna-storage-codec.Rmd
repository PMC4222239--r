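---
title: "Methods: an error-tolerating DNA storage codec"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: an error-tolerating DNA storage codec}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dnastore)
```

## The storage model

`dnastore` implements a DNA-based information storage system built around a
single idea: rather than keeping synthesized DNA fragments short and
redundant to dodge sequencing errors, protect a *long* fragment with a
proper channel code and let the decoder absorb the errors. The pipeline is

1. **Compression.** The payload is compressed with the LZMA dictionary
   coder (`memCompress(type = "xz")`). The compression id is recorded in
   the storage container, so decoding never relies on defaults.
2. **Fragmentation.** The compressed bit stream is cut into `n` disjoint,
   non-overlapping slices of `k` bits (default `n = 6`, `k = 640`). The
   final slice is zero-padded and the padding length stored per fragment.
3. **Channel coding.** Each slice is the information word of a regular
   low-density parity-check (LDPC) code and is systematically encoded into
   a 1392-bit codeword.
4. **DNA mapping.** Bit pairs become quaternary digits, then bases, via
   A=0, T=1, C=2, G=3 (most-significant bit first within a pair, bytes
   traversed most-significant pair first). 1392 bits are 696 bases.
5. **Addressing.** A 24-base header encoding (address, total) with
   threefold digit repetition is prepended. Header + payload = 720 bases,
   the *DNA information block*.

Decoding reverses the path: reads are quality-trimmed and assembled into
per-block consensus sequences (greedy seed extension from the known
headers), each consensus is assigned to an address, payload bases are
mapped back to bits, belief propagation corrects substitutions, fragments
are concatenated in address order, the padding is stripped, the stream is
decompressed, and a CRC-32 recorded at encode time verifies bit-exact
recovery.

## The LDPC code and its parameters

The code is a column-regular Gallager-style construction: every bit
participates in exactly `col_weight = 3` parity checks, rows are filled as
evenly as possible, duplicate columns are re-drawn (two identical columns
would give a minimum distance of 2), and the whole matrix is re-drawn from
the same seeded stream if it is not of full row rank. A systematic encoder
is obtained by Gauss-Jordan elimination over GF(2): non-pivot columns hold
the information bits unchanged, pivot columns the parity bits. Construction
is a pure function of `(n, k, col_weight, seed)`.

The production code has `n = 1392`, `k = 640` (rate 0.46), seed 101. The
choice closes the block-length equation: 24 header bases + 1392/2 payload
bases = 720 bases exactly. At rate 0.46 the code sits far below
binary-symmetric-channel capacity at the error rates of interest, which is
what makes the 4% tolerance target comfortable.

**Channel mapping.** Substitution errors live on bases, the decoder on
bits. A quaternary-symmetric substitution (replacement uniform over the
other three bases) flips each of the base's two bits with probability 2/3,
so decoder LLRs use `p_bit = (2/3) p_base`. Decoding is sum-product belief
propagation on the Tanner graph with hard-decision channel LLRs of
magnitude `log((1-p)/p)`, a flooding schedule, early exit on zero syndrome
and a 100-iteration cap (standard practice; non-convergence is a returned
flag, never an error). Consensus sequences carry no calibrated per-base
qualities, so no soft input is attempted.

The measured behavior of this code (the package's own sweep, seeded): 100%
payload recovery at every grid point of 0-8% base substitution with 20
replicates, a waterfall to partial recovery around 10-12%, and total
failure at 20%. The recovery threshold reported by
`error_tolerance_sweep()` is therefore the grid maximum, 8%, comfortably
above the 4% design target.

**Headers are not LDPC-protected** (they are added after channel coding).
They rely on two cheaper mechanisms: threefold digit repetition, and the
fact that the decoder can enumerate every candidate header. Address
assignment is a global minimum-cost bijective matching between consensus
sequences and candidate headers under Hamming distance — a single corrupted
header therefore cannot steal another block's address, which per-contig
nearest matching allowed at a few percent substitution. Ambiguity that no
matching can resolve (two byte-identical header regions, or more sequences
than addresses) raises a distinct duplicate-address failure, alongside the
missing-address, non-convergence and checksum-mismatch failure classes.

## The assembler

Assembly is greedy overlay-consensus in the SSAKE style, with the block
headers as seeds (`-w 1`, `-m 50` semantics: minimum depth 1, minimum
overlap 50):

* reads are trimmed to their longest all-`>= Q32` prefix; reads shorter
  than 25 bases after trimming, or containing N, are discarded (the
  two-bit alphabet has no N channel);
* reads and their reverse complements are indexed by their leading
  `min_overlap` bases;
* at each step, reads whose prefix matches the contig's 3' suffix by at
  least the minimum overlap vote on the next base; the majority base is
  appended (ties broken deterministically A<C<G<T) if supported by at
  least `min_depth` reads;
* when the 3' end is exhausted the contig is reverse complemented and the
  other end extended; finally all placed reads are piled up and the
  consensus re-called per position by majority vote.

**Seed bootstrap.** A 24-base seed is shorter than a 50-base overlap, so
near the seed no read can formally qualify. While the contig is shorter
than one read length, the overlap floor is relaxed to 16 bases and read
prefixes are scanned directly; the full overlap requirement applies from
one read length onward. Sixteen bases keep random 4^16-fold collisions
negligible while letting reads that start a few bases into the block
participate.

**Why majority voting absorbs indels.** Reads carrying an insertion or
deletion stop matching the contig exactly at the indel and simply stop
contributing votes past it; at reasonable depth the error-free majority
dictates every appended base, so the consensus tracks the reference
without gaps. The package verifies this directly: at 90x simulated
coverage with the observed error profile, the global alignment of
consensus to truth contains zero internal gap columns across seeded
replicates.

## The read simulator

`simulate_read_pairs()` emulates the sequencing geometry of the original
library: 76-base read pairs from 200-base inserts, fragment starts uniform
over valid positions, mate 2 reverse-complemented. Per-base errors follow
an `error_profile()` whose defaults are the observed rates — 0.19%
substitution, 0.01% insertion, 0.38% deletion — applied as one categorical
draw per template position (the rates are tiny, so at most one event per
position is the simplest well-defined composition). Insertions copy a
uniform random base; deletions shorten the read. Qualities are Q40
everywhere except substituted bases, which draw uniformly from Q20-39 so
that the Q32 trimming path does real work; no attempt is made to model a
platform-specific quality spectrum. Pair counts follow
`ceiling(coverage * L / (2 * read_len))`.

What the simulator deliberately does **not** model: the strong per-block
library bias seen in real data (coverage spreads of three orders of
magnitude), GC or positional bias, PCR duplicates, or cycle-dependent
error ramps. Coverage is a clean parameter instead. Consequently, passing
tests show that the codec and assembler behave correctly under the stated
error rates and geometry — not that any particular wet-lab library will
deliver uniform 90x coverage.

One structural property matters for interpreting results: with fragment
starts uniform over `[1, L - insert + 1]`, the terminal reference base is
covered only by fragments starting at exactly one position, so terminal
coverage decays to roughly `coverage/26` at the last base. Assemblies from
random insert-based draws therefore end a few bases short of the block
boundary at moderate coverage. That is a property of the read geometry,
not of the assembler; the assembler-exactness tests use reads laid out to
tile the reference (including both ends), while identity-versus-coverage
results are reported on the realistic insert-based draws.

## The two characterization experiments

**Error tolerance.** `error_tolerance_sweep()` encodes the payload once,
then per grid rate and replicate substitutes every base of every block
independently and attempts full decoding; success means bit-exact payload
recovery (CRC-32 match) — the strictest reading of "complete recovery".
The desk-scale default grid is 0-8% in 0.5% steps with 20 replicates
(2,040 block decodes), which runs in seconds; the threshold is the largest
grid rate with full recovery in all replicates. Replicates share seeds
across grid points and the substitution channel draws its replacement
offsets for all positions up front, so error sets are nested and agree on
shared positions (common random numbers) — this makes the
monotonicity-in-noise test sharp rather than statistical.

**Coverage requirement.** `coverage_sweep()` simulates one read pool per
replicate at just above the maximum requested coverage, then down-samples
by taking nested prefixes of a per-replicate permutation of pairs (pairs
kept or dropped together), mirroring the down-sampling design of the
original study and coupling coverages within a replicate. Each subset is
trimmed, assembled from the header seed, and scored by global-alignment
percent identity against the truth. Identity uses Needleman-Wunsch with
match +1, mismatch -1, gap -2, and `100 * matches / alignment_length`
counting every column — a *global* aligner, where the original study used
a local one (BLAST), because a local aligner would silently ignore exactly
the terminal truncation discussed above. Terminal shortfall therefore
costs identity here, making the criterion conservative. At 90x with the
default profile the package measures mean identities around 99.5-99.9%
over 20 replicates (seeds vary the third digit), against the >= 97%
design target; at 1-2x the contig cannot span the block and identity
collapses.

Desk-scale problem sizes throughout (0.5% grid steps rather than 0.1%, 20
rather than 100 assembly replicates, a handful of spot checks beyond the
waterfall) were chosen so the full suite runs in minutes on one core while
exercising every decision point of the method; all generators accept the
full-scale settings as plain arguments.

## Numerical and degenerate-input choices

* GF(2) elimination is dense integer arithmetic modulo 2; the production
  matrix (752 x 1392) reduces in a few seconds and the constructed code is
  cached per session.
* `tanh`-product check updates are clamped to ±(1 - 1e-13) to keep
  `atanh` finite; a zero message is handled by the exclusion product.
* `p_bit = 0` short-circuits decoding to a syndrome check.
* Empty payloads compress and round-trip; empty read sets assemble to the
  seed itself, flagged short.
* Sequences shorter than header + payload are right-padded with `A` before
  decoding and left to the CRC to reject if genuinely truncated.
* All stochastic components are pure functions of `(input, parameters,
  seed)`; experiment outputs are reproducible bit-for-bit and ship with a
  JSON manifest of their parameters.

## Known limitations

* The codec corrects substitutions only; insertions and deletions must be
  removed upstream by the assembler's majority vote. This matches the
  design under test, but means raw single-molecule reads with high indel
  rates could not be decoded directly without an assembly step.
* Homopolymers are deliberately not avoided; platforms with strong
  homopolymer error modes would stress the assembler more than the
  simulator does.
* The address header carries no error correction beyond repetition; with
  hundreds of blocks (instead of 6) and high substitution rates, header
  matching would become the weakest link before the LDPC code does.
* Assembly uses single-end greedy extension; mate-pair constraints are not
  used to resolve repeats, which is adequate for random-looking coded
  payloads but would not be for low-entropy ones.
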