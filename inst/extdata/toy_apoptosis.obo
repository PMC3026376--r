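format-version: 1.2
ontology: toy

[Term]
id: GO:0008150
name: biological_process
namespace: biological_process
def: "Any process specifically pertinent to the functioning of integrated living units." []

[Term]
id: GO:0006915
name: apoptosis
namespace: biological_process
alt_id: GO:0008632
def: "A form of programmed cell death." []
synonym: "programmed cell death by apoptosis" EXACT []
is_a: GO:0008150 ! biological_process

[Term]
id: GO:0042981
name: regulation of apoptosis
namespace: biological_process
def: "Any process that modulates the occurrence or rate of apoptosis." []
is_a: GO:0008150 ! biological_process

[Term]
id: GO:0043065
name: positive regulation of apoptosis
namespace: biological_process
def: "Any process that activates or increases the frequency of apoptosis." []
is_a: GO:0042981 ! regulation of apoptosis

[Term]
id: GO:0043066
name: negative regulation of apoptosis
namespace: biological_process
def: "Any process that stops or reduces the frequency of apoptosis." []
is_a: GO:0042981 ! regulation of apoptosis

[Term]
id: GO:0006916
name: anti-apoptosis
namespace: biological_process
def: "A process that directly inhibits the execution of the apoptotic program." []
is_a: GO:0043066 ! negative regulation of apoptosis
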