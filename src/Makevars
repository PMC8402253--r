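# The transport kernel is the package's hot loop; place our flags after
# $(CXXFLAGS) so they take effect (notably -fno-stack-protector, which
# measurably slows the per-step loop when forced by the site profile).
PKG_CXXFLAGS = -O3 -fno-math-errno -fno-stack-protector
ALL_CXXFLAGS = $(R_XTRA_CXXFLAGS) $(CXXPICFLAGS) $(SHLIB_CXXFLAGS) $(CXXFLAGS) $(PKG_CXXFLAGS)
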