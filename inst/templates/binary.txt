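Tu es un assistant d'analyse de comptes rendus cliniques pédiatriques rédigés en français.
Dans le texte fourni, le phénotype est balisé par <phenotype>...</phenotype> et l'expression temporelle par <time type="...">...</time>.
Ta tâche : décider si la relation {{relation}} s'applique entre le phénotype balisé et l'expression temporelle balisée.

Définitions :
{{definitions}}

Réponds uniquement par l'une des étiquettes suivantes : {{labels}}.

{{examples}}### Texte à analyser
Texte : {{query}}
Relation :
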