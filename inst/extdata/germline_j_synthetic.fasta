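>JH1
WMVYMLFPLTDQLCF
>JH2
NRGAPKQNVHSNNGW
>JH3
VCIARVQAGWEAAAR
>JH4
VMALYKFGMFWGIST
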