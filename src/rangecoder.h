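#ifndef FQCM_RANGECODER_H
#define FQCM_RANGECODER_H

#include <cstdint>
#include <vector>
#include <stdexcept>

// Adaptive binary / multi-symbol range coder.
//
// 32-bit range register, 16-bit probabilities, byte-wise renormalization at
// 2^24, explicit carry propagation into the already-emitted buffer, 4-byte
// flush.  Integer-only: identical payloads across platforms.  The decoder
// consumes exactly the bytes the encoder emitted, so truncation is always
// detectable (out-of-bounds read, or leftover bytes checked by the caller).

namespace fqcm {

constexpr uint32_t RC_TOP = 1u << 24;
constexpr uint32_t RC_PROB_ONE = 1u << 16;  // probabilities are /65536

class RangeEncoder {
public:
    std::vector<uint8_t> out;

    RangeEncoder() : low_(0), range_(0xFFFFFFFFu) {}

    // Encode a symbol with cumulative frequency cf, frequency f (> 0) out of
    // total tot (tot <= 65536).
    void encode(uint32_t cf, uint32_t f, uint32_t tot) {
        uint32_t unit = range_ / tot;
        add_low((uint64_t)unit * cf);
        range_ = unit * f;
        normalize();
    }

    // Encode one bit with p1 = P(bit == 1) in [1, 65535].
    void encode_bit(int bit, uint32_t p1) {
        uint32_t bound = (range_ >> 16) * p1;
        if (bit) {
            range_ = bound;
        } else {
            add_low(bound);
            range_ -= bound;
        }
        normalize();
    }

    void flush() {
        for (int i = 0; i < 4; ++i) {
            out.push_back((uint8_t)(low_ >> 24));
            low_ = (low_ << 8) & 0xFFFFFFFFu;
        }
    }

private:
    uint64_t low_;    // kept < 2^32 between operations
    uint32_t range_;

    void add_low(uint64_t x) {
        low_ += x;
        if (low_ >> 32) {  // carry into already-emitted bytes
            size_t i = out.size();
            for (;;) {
                if (i == 0) throw std::runtime_error("range coder carry underflow");
                --i;
                if (out[i] != 0xFF) { ++out[i]; break; }
                out[i] = 0x00;
            }
            low_ &= 0xFFFFFFFFu;
        }
    }

    void normalize() {
        while (range_ < RC_TOP) {
            out.push_back((uint8_t)(low_ >> 24));
            low_ = (low_ << 8) & 0xFFFFFFFFu;
            range_ <<= 8;
        }
    }
};

class RangeDecoder {
public:
    RangeDecoder(const uint8_t* buf, size_t len)
        : buf_(buf), len_(len), pos_(0), range_(0xFFFFFFFFu), code_(0) {
        for (int i = 0; i < 4; ++i) code_ = (code_ << 8) | next_byte();
    }

    // Locate the target cumulative-frequency slot, in [0, tot).
    uint32_t decode_target(uint32_t tot) {
        unit_ = range_ / tot;
        uint32_t dv = code_ / unit_;
        return dv >= tot ? tot - 1 : dv;
    }

    // Commit the symbol found for the last decode_target() call.
    void decode_update(uint32_t cf, uint32_t f) {
        code_ -= unit_ * cf;
        range_ = unit_ * f;
        normalize();
    }

    int decode_bit(uint32_t p1) {
        uint32_t bound = (range_ >> 16) * p1;
        int bit;
        if (code_ < bound) {
            bit = 1;
            range_ = bound;
        } else {
            bit = 0;
            code_ -= bound;
            range_ -= bound;
        }
        normalize();
        return bit;
    }

    size_t consumed() const { return pos_; }
    bool overrun() const { return pos_ > len_; }
    // a decode is clean iff the payload was consumed exactly
    bool clean(size_t payload_len) const { return !overrun() && pos_ == payload_len; }

private:
    const uint8_t* buf_;
    size_t len_, pos_;
    uint32_t range_, code_, unit_;

    uint8_t next_byte() {
        if (pos_ >= len_) { ++pos_; return 0; }  // overrun flagged, decode continues
        return buf_[pos_++];
    }

    void normalize() {
        while (range_ < RC_TOP) {
            code_ = (code_ << 8) | next_byte();
            range_ <<= 8;
        }
    }
};

// 64-bit FNV-1a checksum
inline uint64_t fnv1a64(const uint8_t* p, size_t n, uint64_t h = 0xcbf29ce484222325ULL) {
    for (size_t i = 0; i < n; ++i) {
        h ^= p[i];
        h *= 0x100000001b3ULL;
    }
    return h;
}

} // namespace fqcm

#endif
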