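#include <Rcpp.h>
#include <cmath>
#include "rangecoder.h"

using namespace Rcpp;
using namespace fqcm;

// Context-mixing quality-score codec.
//
// Each quality symbol (ASCII 33..126, i.e. value 0..93) is binarized to 7
// bits, MSB first.  For each bit, six context models predict P(bit == 1)
// from previously decoded history only:
//   0: bit-tree node alone (order-0 over symbols)
//   1: previous score q1
//   2: (q1, q2)
//   3: log-quantized position in the read
//   4: (q1, max of the last 8 scores)
//   5: sign of the running delta q1 - q2
// A logistic mixer (weights selected by a q1 bucket) combines the stretched
// predictions; the shared binary range coder codes the bit.  Predictions are
// 12-bit probabilities in the PAQ tradition; mixing is fixed-point.

namespace {

constexpr int NPRED = 6;
constexpr int QALPHA = 95;   // 94 symbols + start sentinel
constexpr int SENTINEL = 94;

struct StretchSquash {
    int16_t stretch_tab[4096];
    uint16_t squash_tab[4096];  // index x + 2048, x in [-2048, 2047]
    StretchSquash() {
        for (int x = -2048; x < 2048; ++x) {
            double v = 4096.0 / (1.0 + std::exp(-x / 256.0));
            int iv = (int)std::lround(v);
            if (iv < 1) iv = 1;
            if (iv > 4095) iv = 4095;
            squash_tab[x + 2048] = (uint16_t)iv;
        }
        for (int p = 0; p < 4096; ++p) {
            double pp = (p < 1 ? 1 : p) / 4096.0;
            double v = 256.0 * std::log(pp / (1.0 - pp));
            int iv = (int)std::lround(v);
            if (iv < -2047) iv = -2047;
            if (iv > 2047) iv = 2047;
            stretch_tab[p] = (int16_t)iv;
        }
    }
};
const StretchSquash SS;

inline int squash12(int x) {
    if (x < -2047) x = -2047;
    if (x > 2047) x = 2047;
    return SS.squash_tab[x + 2048];
}

struct QualityCM {
    // predictor tables of 12-bit probabilities
    std::vector<uint16_t> t0, t1, t2, t3, t4, t5;
    std::vector<int32_t> w;  // mixer weights: bucket * NPRED + i
    int enabled[NPRED];
    int pred_shift;    // predictor learning rate = 1 / 2^pred_shift
    int mix_shift;     // weight update shift (eta = 1/512 at defaults)
    int n_buckets;
    int pos_buckets;
    double bits = 0;

    // per-read context state
    int q1 = SENTINEL, q2 = SENTINEL;
    int last8[8];
    int n8 = 0, pos = 0;

    QualityCM(LogicalVector pred_mask, int pred_shift_, int mix_shift_,
              int n_buckets_, int pos_buckets_)
        : pred_shift(pred_shift_), mix_shift(mix_shift_),
          n_buckets(n_buckets_), pos_buckets(pos_buckets_) {
        for (int i = 0; i < NPRED; ++i)
            enabled[i] = (i < pred_mask.size() && pred_mask[i]) ? 1 : 0;
        t0.assign(128, 2048);
        t1.assign(QALPHA * 128, 2048);
        t2.assign(1 << 16, 2048);
        t3.assign((size_t)pos_buckets * 128, 2048);
        t4.assign(1 << 16, 2048);
        t5.assign(3 * 128, 2048);
        w.assign((size_t)n_buckets * NPRED, 65536 / NPRED);
        reset_read();
    }

    void reset_read() {
        q1 = SENTINEL;
        q2 = SENTINEL;
        n8 = 0;
        pos = 0;
    }

    inline int posbucket() const {
        int t = pos, b = 0;
        while (t > 0 && b < pos_buckets - 1) { t >>= 1; ++b; }
        return b;
    }

    inline int max8() const {
        if (n8 == 0) return SENTINEL;
        int m = last8[0];
        int n = n8 < 8 ? n8 : 8;
        for (int i = 1; i < n; ++i)
            if (last8[i] > m) m = last8[i];
        return m;
    }

    inline int deltasign() const {
        if (q1 == SENTINEL || q2 == SENTINEL || q1 == q2) return 1;
        return q1 > q2 ? 2 : 0;
    }

    inline uint32_t hash16(uint32_t key, uint32_t node) const {
        uint32_t h = key * 2654435761u + node * 0x9E3779B1u;
        return (h ^ (h >> 15)) & 0xFFFF;
    }

    // returns p16 for the coder; fills slots/st for the update step
    uint32_t predict(int node, int mixsel, size_t* slot, int* st, int* p12mix) {
        uint16_t* tabs[NPRED] = {t0.data(), t1.data(), t2.data(),
                                 t3.data(), t4.data(), t5.data()};
        slot[0] = (size_t)node;
        slot[1] = (size_t)q1 * 128 + node;
        slot[2] = hash16((uint32_t)(q1 * QALPHA + q2), (uint32_t)node);
        slot[3] = (size_t)posbucket() * 128 + node;
        slot[4] = hash16((uint32_t)(q1 * QALPHA + max8()) + 0x5bd1e995u, (uint32_t)node);
        slot[5] = (size_t)deltasign() * 128 + node;
        int64_t dot = 0;
        const int32_t* wr = &w[(size_t)mixsel * NPRED];
        for (int i = 0; i < NPRED; ++i) {
            if (!enabled[i]) { st[i] = 0; continue; }
            int p12 = tabs[i][slot[i]];
            st[i] = SS.stretch_tab[p12];
            dot += (int64_t)wr[i] * st[i];
        }
        int x = (int)(dot >> 16);
        int pm = squash12(x);
        *p12mix = pm;
        uint32_t p16 = (uint32_t)pm << 4;
        if (p16 < 1) p16 = 1;
        if (p16 > 65535) p16 = 65535;
        return p16;
    }

    void update(int bit, int node, int mixsel, const size_t* slot,
                const int* st, int p12mix) {
        uint16_t* tabs[NPRED] = {t0.data(), t1.data(), t2.data(),
                                 t3.data(), t4.data(), t5.data()};
        int err = (bit << 12) - p12mix;
        int32_t* wr = &w[(size_t)mixsel * NPRED];
        for (int i = 0; i < NPRED; ++i) {
            if (!enabled[i]) continue;
            wr[i] += (err * st[i]) >> mix_shift;
            int p = tabs[i][slot[i]];
            p += ((bit << 12) - p) >> pred_shift;
            if (p < 1) p = 1;
            if (p > 4095) p = 4095;
            tabs[i][slot[i]] = (uint16_t)p;
        }
    }

    inline int mixsel() const {
        int b = q1 == SENTINEL ? 0 : (q1 * n_buckets) / QALPHA;
        if (b >= n_buckets) b = n_buckets - 1;
        return b;
    }

    void push_symbol(int val) {
        q2 = q1;
        q1 = val;
        last8[n8 % 8] = val;
        ++n8;
        ++pos;
    }
};

} // namespace

// [[Rcpp::export]]
List qual_encode_(CharacterVector quals, LogicalVector pred_mask, int pred_shift,
                  int mix_shift, int n_buckets, int pos_buckets) {
    QualityCM cm(pred_mask, pred_shift, mix_shift, n_buckets, pos_buckets);
    RangeEncoder enc;
    NumericVector bits_per_read(quals.size());
    size_t slot[NPRED];
    int st[NPRED], p12;

    for (int r = 0; r < quals.size(); ++r) {
        const char* s = CHAR(STRING_ELT(quals, r));
        cm.reset_read();
        double bits0 = cm.bits;
        for (int i = 0; s[i]; ++i) {
            uint8_t b = (uint8_t)s[i];
            if (b < 33 || b > 126)
                stop("quality symbol outside ASCII 33-126 in record %d position %d",
                     r + 1, i + 1);
            int val = b - 33;
            int node = 1;
            int sel = cm.mixsel();
            for (int k = 6; k >= 0; --k) {
                int bit = (val >> k) & 1;
                uint32_t p16 = cm.predict(node, sel, slot, st, &p12);
                enc.encode_bit(bit, p16);
                cm.bits += -std::log2(bit ? p16 / 65536.0 : 1.0 - p16 / 65536.0);
                cm.update(bit, node, sel, slot, st, p12);
                node = node * 2 + bit;
            }
            cm.push_symbol(val);
        }
        bits_per_read[r] = cm.bits - bits0;
    }
    enc.flush();
    return List::create(
        _["payload"] = RawVector(enc.out.begin(), enc.out.end()),
        _["bits_per_read"] = bits_per_read,
        _["total_bits"] = cm.bits);
}

// [[Rcpp::export]]
CharacterVector qual_decode_(RawVector payload, IntegerVector lengths,
                             LogicalVector pred_mask, int pred_shift,
                             int mix_shift, int n_buckets, int pos_buckets) {
    QualityCM cm(pred_mask, pred_shift, mix_shift, n_buckets, pos_buckets);
    RangeDecoder dec((const uint8_t*)RAW(payload), payload.size());
    CharacterVector outv(lengths.size());
    std::string buf;
    size_t slot[NPRED];
    int st[NPRED], p12;

    for (int r = 0; r < lengths.size(); ++r) {
        int len = lengths[r];
        cm.reset_read();
        buf.assign((size_t)len, ' ');
        for (int i = 0; i < len; ++i) {
            int node = 1;
            int sel = cm.mixsel();
            for (int k = 6; k >= 0; --k) {
                uint32_t p16 = cm.predict(node, sel, slot, st, &p12);
                int bit = dec.decode_bit(p16);
                cm.update(bit, node, sel, slot, st, p12);
                node = node * 2 + bit;
            }
            int val = node - 128;
            if (val < 0 || val > 93)
                stop("corrupt quality payload: symbol value %d out of range", val);
            buf[i] = (char)(val + 33);
            cm.push_symbol(val);
        }
        outv[r] = buf;
    }
    if (!dec.clean(payload.size()))
        stop("corrupt or truncated quality payload (consumed %d of %d bytes)",
             (int)dec.consumed(), (int)payload.size());
    return outv;
}

// ---- logistic link surface (exposed for the mixing contract) ----------------

// [[Rcpp::export]]
double cm_stretch_(double p) {
    if (!(p > 0.0 && p < 1.0)) stop("stretch is defined on (0, 1)");
    int p12 = (int)std::lround(p * 4096.0);
    if (p12 < 1) p12 = 1;
    if (p12 > 4095) p12 = 4095;
    return SS.stretch_tab[p12] / 256.0;
}

// [[Rcpp::export]]
double cm_squash_(double x) {
    int xi = (int)std::lround(x * 256.0);
    return squash12(xi) / 4096.0;
}
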