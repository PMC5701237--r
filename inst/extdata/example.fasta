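>RP_example A small ribosomal protein used as the worked attribute-extraction example
MGKVHGSLARAGKVRGQTPKVAKQEKKKQPKGRAFQRIKYNRRFVNVVVGIGKKRSPNSNQA
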