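>alpha_closed_reference synthetic consensus of a closed-form cryptophyte alpha subunit
APNTDFSKAVGCARGDLSSEAAVSWDKWAGLSNEQNAIVKAGGKAMDAAFAKAGVSPSEASKLVAGH
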