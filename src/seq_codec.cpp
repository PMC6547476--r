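#include <Rcpp.h>
#include <cmath>
#include "rangecoder.h"

using namespace Rcpp;
using namespace fqcm;

// Competing finite-context models over the {A,C,G,T} alphabet, blended by
// recent coding performance, feeding the shared range coder.  Non-ACGT bytes
// are handled with a per-position binary escape flag plus a literal channel
// (order-0 adaptive byte model) in the same coded stream.

namespace {

constexpr int NBASE = 4;

inline int base_code(uint8_t b) {
    switch (b) {
        case 'A': return 0;
        case 'C': return 1;
        case 'G': return 2;
        case 'T': return 3;
        default:  return -1;
    }
}
const char BASE_CHR[4] = {'A', 'C', 'G', 'T'};

// one order-k model; exact table for k <= 8, hashed 4-symbol rows above
struct NucModel {
    int order;
    bool hashed;
    uint32_t mask;          // context mask (2k bits) for exact, table mask for hashed
    uint64_t ctx_mask;      // 2k-bit history mask
    std::vector<uint16_t> counts;  // slot*4 + base

    NucModel(int k, int hash_bits) : order(k) {
        ctx_mask = (k >= 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
        hashed = k > 8;
        if (!hashed) {
            size_t nctx = (size_t)1 << (2 * k);
            mask = (uint32_t)(nctx - 1);
            counts.assign(nctx * 4, 0);
        } else {
            size_t nctx = (size_t)1 << hash_bits;
            mask = (uint32_t)(nctx - 1);
            counts.assign(nctx * 4, 0);
        }
    }

    inline size_t slot(uint64_t hist) const {
        uint64_t ctx = hist & ctx_mask;
        if (!hashed) return (size_t)ctx;
        uint64_t h = ctx * 0x9E3779B97F4A7C15ULL;
        return (size_t)((h >> 40) & mask);
    }

    inline void probs(uint64_t hist, double alpha, double* p) const {
        const uint16_t* row = &counts[slot(hist) * 4];
        double tot = (double)row[0] + row[1] + row[2] + row[3] + 4.0 * alpha;
        for (int s = 0; s < 4; ++s) p[s] = (row[s] + alpha) / tot;
    }

    inline void update(uint64_t hist, int s) {
        uint16_t* row = &counts[slot(hist) * 4];
        if (row[s] >= 65500) {
            for (int j = 0; j < 4; ++j) row[j] >>= 1;
        }
        row[s] += 1;
    }
};

struct AdaptiveBit {
    uint16_t p = 32768;  // P(bit==1) / 65536
    inline uint32_t prob() const { return p; }
    inline void update(int bit) {
        if (bit) p += (65535 - p) >> 5;
        else p -= p >> 5;
        if (p < 1) p = 1;
        if (p > 65535) p = 65535;
    }
};

struct SeqCoder {
    std::vector<NucModel> models;
    std::vector<double> perf;   // decayed code length per model, bits
    double alpha, decay;
    uint64_t hist = 0;
    AdaptiveBit esc[2];         // escape flag, context = previous flag
    int last_esc = 0;
    std::vector<uint32_t> lit_counts;  // order-0 literal byte model
    uint32_t lit_total;
    double bits = 0;            // model entropy accounting

    SeqCoder(IntegerVector orders, double alpha_, double decay_, int hash_bits)
        : alpha(alpha_), decay(decay_), lit_counts(256, 1), lit_total(256) {
        for (int i = 0; i < orders.size(); ++i)
            models.emplace_back(orders[i], hash_bits);
        perf.assign(models.size(), 0.0);
    }

    // blended, quantized frequencies over ACGT (sum == 65536, all >= 1)
    void blended_freqs(uint32_t* f, double* pm /* nmodels x 4 scratch */) {
        int nm = (int)models.size();
        double minp = perf[0];
        for (int m = 1; m < nm; ++m) if (perf[m] < minp) minp = perf[m];
        double wsum = 0;
        std::vector<double> w(nm);
        for (int m = 0; m < nm; ++m) {
            double e = perf[m] - minp;
            w[m] = std::exp2(e > 40.0 ? -40.0 : -e) + 1e-4;
            wsum += w[m];
        }
        double p[4] = {0, 0, 0, 0};
        for (int m = 0; m < nm; ++m) {
            models[m].probs(hist, alpha, pm + 4 * m);
            double wm = w[m] / wsum;
            for (int s = 0; s < 4; ++s) p[s] += wm * pm[4 * m + s];
        }
        uint32_t tot = 0;
        int amax = 0;
        for (int s = 0; s < 4; ++s) {
            f[s] = (uint32_t)(p[s] * 65532.0);
            if (f[s] < 1) f[s] = 1;
            tot += f[s];
            if (f[s] > f[amax]) amax = s;
        }
        f[amax] += 65536 - tot;  // exact renormalization
    }

    void account_and_update(const uint32_t* f, const double* pm, int s) {
        bits += -std::log2((double)f[s] / 65536.0);
        int nm = (int)models.size();
        for (int m = 0; m < nm; ++m)
            perf[m] = decay * perf[m] + (-std::log2(pm[4 * m + s]));
        for (int m = 0; m < nm; ++m) models[m].update(hist, s);
        hist = (hist << 2) | (uint64_t)s;
    }

    void literal_freq(int b, uint32_t& cf, uint32_t& fr, uint32_t& tot) const {
        uint32_t c = 0;
        for (int j = 0; j < b; ++j) c += lit_counts[j];
        cf = c;
        fr = lit_counts[b];
        tot = lit_total;
    }

    int literal_find(uint32_t dv, uint32_t& cf, uint32_t& fr) const {
        uint32_t c = 0;
        int b = 0;
        for (;;) {
            if (c + lit_counts[b] > dv) { cf = c; fr = lit_counts[b]; return b; }
            c += lit_counts[b];
            ++b;
        }
    }

    void literal_update(int b) {
        lit_counts[b] += 24;
        lit_total += 24;
        if (lit_total > 60000) {
            lit_total = 0;
            for (int j = 0; j < 256; ++j) {
                lit_counts[j] = (lit_counts[j] >> 1) | 1;
                lit_total += lit_counts[j];
            }
        }
    }
};

} // namespace

// [[Rcpp::export]]
List seq_encode_(CharacterVector seqs, IntegerVector orders, double alpha,
                 double decay, int hash_bits) {
    SeqCoder sc(orders, alpha, decay, hash_bits);
    RangeEncoder enc;
    int nm = (int)sc.models.size();
    std::vector<double> pm(4 * nm);
    uint32_t f[4];
    NumericVector bits_per_read(seqs.size());

    for (int r = 0; r < seqs.size(); ++r) {
        const char* s = CHAR(STRING_ELT(seqs, r));
        double bits0 = sc.bits;
        for (const char* q = s; *q; ++q) {
            uint8_t b = (uint8_t)*q;
            int code = base_code(b);
            int is_esc = (code < 0);
            // escape flag
            uint32_t pe = sc.esc[sc.last_esc].prob();
            enc.encode_bit(is_esc, pe);
            sc.bits += -std::log2(is_esc ? pe / 65536.0 : 1.0 - pe / 65536.0);
            sc.esc[sc.last_esc].update(is_esc);
            sc.last_esc = is_esc;
            if (is_esc) {
                if (b < 33 || b > 126)
                    stop("sequence byte %d outside printable ASCII", (int)b);
                uint32_t cf, fr, tot;
                sc.literal_freq(b, cf, fr, tot);
                enc.encode(cf, fr, tot);
                sc.bits += -std::log2((double)fr / tot);
                sc.literal_update(b);
                sc.hist = (sc.hist << 2);  // push placeholder A into history
            } else {
                sc.blended_freqs(f, pm.data());
                uint32_t cf = 0;
                for (int j = 0; j < code; ++j) cf += f[j];
                enc.encode(cf, f[code], 65536);
                sc.account_and_update(f, pm.data(), code);
            }
        }
        bits_per_read[r] = sc.bits - bits0;
    }
    enc.flush();
    return List::create(
        _["payload"] = RawVector(enc.out.begin(), enc.out.end()),
        _["bits_per_read"] = bits_per_read,
        _["total_bits"] = sc.bits);
}

// [[Rcpp::export]]
CharacterVector seq_decode_(RawVector payload, IntegerVector lengths,
                            IntegerVector orders, double alpha, double decay,
                            int hash_bits) {
    SeqCoder sc(orders, alpha, decay, hash_bits);
    RangeDecoder dec((const uint8_t*)RAW(payload), payload.size());
    int nm = (int)sc.models.size();
    std::vector<double> pm(4 * nm);
    uint32_t f[4];
    CharacterVector outv(lengths.size());
    std::string buf;

    for (int r = 0; r < lengths.size(); ++r) {
        int len = lengths[r];
        buf.assign((size_t)len, ' ');
        for (int i = 0; i < len; ++i) {
            uint32_t pe = sc.esc[sc.last_esc].prob();
            int is_esc = dec.decode_bit(pe);
            sc.esc[sc.last_esc].update(is_esc);
            sc.last_esc = is_esc;
            if (is_esc) {
                uint32_t tot = sc.lit_total;
                uint32_t dv = dec.decode_target(tot);
                uint32_t cf, fr;
                int b = sc.literal_find(dv, cf, fr);
                dec.decode_update(cf, fr);
                sc.literal_update(b);
                sc.hist = (sc.hist << 2);
                buf[i] = (char)b;
            } else {
                sc.blended_freqs(f, pm.data());
                uint32_t dv = dec.decode_target(65536);
                uint32_t cf = 0;
                int code = 0;
                while (cf + f[code] <= dv) { cf += f[code]; ++code; }
                dec.decode_update(cf, f[code]);
                sc.account_and_update(f, pm.data(), code);
                buf[i] = BASE_CHR[code];
            }
        }
        outv[r] = buf;
    }
    if (!dec.clean(payload.size()))
        stop("corrupt or truncated sequence payload (consumed %d of %d bytes)",
             (int)dec.consumed(), (int)payload.size());
    return outv;
}
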