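key	value
config_md5	00e54ead0889d852f7a4f3d9fa724dd4
seed	7
package_version	1.0.0
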