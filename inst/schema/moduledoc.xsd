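<?xml version="1.0" encoding="UTF-8"?>
<xs:schema xmlns:xs="http://www.w3.org/2001/XMLSchema" elementFormDefault="unqualified">

  <xs:simpleType name="identifier">
    <xs:restriction base="xs:string">
      <xs:pattern value="[A-Za-z_][A-Za-z0-9_.-]*"/>
    </xs:restriction>
  </xs:simpleType>

  <xs:element name="moduleDocumentation">
    <xs:complexType>
      <xs:sequence>
        <xs:element name="description" type="xs:string" minOccurs="0"/>
        <xs:element name="paperDescription" type="xs:string" minOccurs="0"/>
        <xs:element name="dependency" minOccurs="0" maxOccurs="unbounded">
          <xs:complexType>
            <xs:attribute name="software" type="xs:string" use="required"/>
            <xs:attribute name="version" type="xs:string"/>
          </xs:complexType>
        </xs:element>
        <xs:element name="pmid" type="xs:positiveInteger" minOccurs="0" maxOccurs="unbounded"/>
        <xs:element name="category" type="xs:string" minOccurs="0" maxOccurs="unbounded"/>
        <xs:element name="author" type="xs:string" minOccurs="0" maxOccurs="unbounded"/>
        <xs:element name="paramDoc" minOccurs="0" maxOccurs="unbounded">
          <xs:complexType>
            <xs:simpleContent>
              <xs:extension base="xs:string">
                <xs:attribute name="name" type="identifier" use="required"/>
                <xs:attribute name="default" type="xs:string"/>
                <xs:attribute name="minVersion" type="xs:positiveInteger"/>
                <xs:attribute name="maxVersion" type="xs:positiveInteger"/>
              </xs:extension>
            </xs:simpleContent>
          </xs:complexType>
        </xs:element>
        <xs:element name="returnDoc" minOccurs="0" maxOccurs="unbounded">
          <xs:complexType>
            <xs:simpleContent>
              <xs:extension base="xs:string">
                <xs:attribute name="name" type="identifier" use="required"/>
                <xs:attribute name="minVersion" type="xs:positiveInteger"/>
                <xs:attribute name="maxVersion" type="xs:positiveInteger"/>
              </xs:extension>
            </xs:simpleContent>
          </xs:complexType>
        </xs:element>
      </xs:sequence>
      <xs:attribute name="module" type="identifier" use="required"/>
    </xs:complexType>
  </xs:element>
</xs:schema>
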